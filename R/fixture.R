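## Default study fixture: a 1 Mb two-chromosome genome with 24 planted piRNA
## clusters (10 TE-block, 8 intergenic, 6 genic) and five stage libraries
## (BC, PGC, E11G, E14G, AT) of 200 k reads each. Cluster stage weights follow
## the developmental trend of the system under study: blastoderm piRNAs almost
## entirely TE-derived, adult-testis piRNAs predominantly intergenic and
## shorter, embryonic gonads in between with the largest genic share.

#' Default contaminant depths per simulated library
#'
#' Oxidation-enriched libraries are piRNA-dominated; rRNA/tRNA-derived reads
#' are the largest contaminant class, miRNAs are strongly depleted, and
#' genomic degradation is rare and uniform. The degradation rate is kept
#' below one read per `max_gap` of genome so the gap-based cluster detector's
#' sparse-background assumption holds.
#'
#' @return named list of read counts.
#' @export
default_noise <- function() {
  list(degradation = 100, rrna = 4000, trna = 2000, mirna = 2000,
       pred_mirna = 1000)
}

## per-group emission probability by stage (columns sum to 1)
fixture_group_weights <- function() {
  m <- rbind(TE        = c(BC = 0.93, PGC = 0.35, E11G = 0.30, E14G = 0.28,
                           AT = 0.16),
             genic     = c(BC = 0.04, PGC = 0.15, E11G = 0.23, E14G = 0.23,
                           AT = 0.12),
             intergenic = c(BC = 0.03, PGC = 0.50, E11G = 0.47, E14G = 0.49,
                            AT = 0.72))
  m
}

#' Cluster specifications of the default fixture
#'
#' Derives planted-cluster specs from a reference bundle: the TE blocks
#' become TE clusters (two of them BC-specific), eight intergenic slots
#' become intergenic clusters (two AT-specific, shorter reads, ping-pong
#' active; one PGC-specific), and six TE-free genes become genic clusters
#' (two specific to the embryonic-gonad stages).
#'
#' @param bundle a `pr_bundle` built with the default parameters.
#' @return list of [cluster_spec()] objects.
#' @export
default_fixture_specs <- function(bundle) {
  stages <- c("BC", "PGC", "E11G", "E14G", "AT")
  gw <- fixture_group_weights()
  specific <- function(stage_set, hi = 6, lo = 0.05) {
    r <- setNames(rep(lo, length(stages)), stages)
    r[stage_set] <- hi
    r
  }
  shared <- setNames(rep(1, length(stages)), stages)

  make_group <- function(spans, group, rel, modes, pp, len_mean, len_sd) {
    rel_mat <- do.call(rbind, rel)              # clusters x stages
    share <- sweep(rel_mat, 2L, colSums(rel_mat), "/")
    lapply(seq_len(nrow(spans)), function(i) {
      w <- gw[group, stages] * share[i, stages]
      cluster_spec(spans$chrom[i], spans$start[i], spans$end[i],
                   mode = modes[i], stage_weights = w,
                   u1_prob = 0.9, pingpong_frac = pp[i],
                   length_mean = len_mean[i], length_sd = len_sd[i],
                   region_type = if (group == "TE") "TE"
                                 else if (group == "genic") "genic"
                                 else "intergenic",
                   cluster_id = sprintf("%s_%02d", group, i))
    })
  }

  ## TE-block clusters (5): two BC-specific mono, one shared mono, two
  ## shared dual-strand with active ping-pong
  blocks <- bundle$te[placement == "block",
                      .(chrom = chrom[1L], start = min(start), end = max(end)),
                      by = block_id]
  data.table::setorder(blocks, block_id)
  if (nrow(blocks) < 5L) stopf("default fixture needs >= 5 TE blocks")
  blocks <- head(blocks, 5L)
  te_rel <- c(list(specific("BC"), specific("BC")), rep(list(shared), 3L))
  te_modes <- c("mono_plus", "mono_minus", "mono_plus", "dual_strand",
                "dual_strand")
  te_pp <- c(0.05, 0.05, 0.05, 0.25, 0.25)
  te_specs <- make_group(blocks, "TE", te_rel, te_modes, te_pp,
                         rep(27.5, 5L), rep(1.0, 5L))

  ## genic clusters (3): interior of TE-free genes with span >= 2.5 kb
  with_te <- bundle$genes$transcript_id %in% overlapping_tx(bundle)
  g <- bundle$genes[!with_te & (end - start) >= 2500][order(transcript_id)]
  g <- head(g, 3L)
  if (nrow(g) < 3L) stopf("default fixture needs >= 3 TE-free genes")
  pad <- floor((g$end - g$start) * 0.2)
  genic_spans <- data.table::data.table(chrom = g$chrom,
                                        start = g$start + pad,
                                        end = g$end - pad)
  genic_rel <- list(specific(c("E11G", "E14G")), specific(c("E11G", "E14G")),
                    specific("PGC"))
  sense <- c(TRUE, FALSE, TRUE)        # alternate sense/antisense emission
  genic_modes <- ifelse(sense == (g$strand == "+"), "mono_plus", "mono_minus")
  genic_specs <- make_group(genic_spans, "genic", genic_rel, genic_modes,
                            rep(0, 3L), rep(27.5, 3L), rep(1.0, 3L))

  ## intergenic clusters (4): slots kept >= 12 kb from every cluster-hosting
  ## feature and from each other, so planted clusters stay separable under
  ## the detector's inter-read gap threshold
  ig_spans <- spaced_intergenic_slots(bundle, n = 4L, slot_len = 4000L,
                                      isolation = 12000L)
  ig_rel <- c(list(specific("AT"), specific("AT")), rep(list(shared), 2L))
  ig_modes <- c("mono_plus", "mono_minus", "bidirectional", "mono_minus")
  ig_pp <- c(0.15, 0.15, 0.2, 0.05)
  ig_len <- c(25.5, 25.5, 27.5, 27.5)
  ig_specs <- make_group(ig_spans, "intergenic", ig_rel, ig_modes, ig_pp,
                         ig_len, rep(1.0, 4L))

  c(te_specs, genic_specs, ig_specs)
}

## non-overlapping intergenic slots for planted clusters, isolated from
## read-emitting features (genes, TE blocks) and from each other
spaced_intergenic_slots <- function(bundle, n, slot_len = 4000L,
                                    isolation = 12000L, other_margin = 300L) {
  free <- lapply(names(bundle$genome), function(ch) {
    L <- length(bundle$genome[[ch]])
    pad_ir <- function(tab, pad) {
      tab <- tab[tab$chrom == ch, ]
      if (!nrow(tab)) return(IRanges::IRanges())
      IRanges::IRanges(pmax(tab$start + 1L - pad, 1L),
                       pmin(tab$end + pad, L))
    }
    hosts <- rbind(bundle$te[placement == "block", .(chrom, start, end)],
                   bundle$genes[, .(chrom, start, end)])
    occ <- IRanges::reduce(c(pad_ir(hosts, isolation),
                             pad_ir(bundle$te[placement != "block"],
                                    other_margin),
                             pad_ir(bundle$ncrna, other_margin)))
    gap <- IRanges::setdiff(IRanges::IRanges(1L, L), occ)
    gap <- gap[IRanges::width(gap) >= slot_len + 600L]
    data.table::data.table(chrom = ch, start = IRanges::start(gap) - 1L,
                           end = IRanges::end(gap))
  })
  free <- data.table::rbindlist(free)
  data.table::setorder(free, chrom, start)
  slots <- list()
  last_chrom <- ""; last_end <- -Inf
  for (i in seq_len(nrow(free))) {
    at <- free$start[i] + 300L
    if (free$chrom[i] == last_chrom)
      at <- max(at, as.integer(last_end + isolation))
    while (at + slot_len <= free$end[i] - 300L && length(slots) < n) {
      slots[[length(slots) + 1L]] <- data.table::data.table(
        chrom = free$chrom[i], start = at, end = at + slot_len)
      last_chrom <- free$chrom[i]; last_end <- at + slot_len
      at <- as.integer(last_end + isolation)
    }
    if (length(slots) >= n) break
  }
  if (length(slots) < n)
    stopf("default fixture needs %d isolated intergenic slots, found %d",
          n, length(slots))
  data.table::rbindlist(slots)
}

## transcripts overlapping any TE copy
overlapping_tx <- function(bundle) {
  if (!nrow(bundle$te)) return(character())
  h <- GenomicRanges::findOverlaps(
    gr0(bundle$genes$chrom, bundle$genes$start, bundle$genes$end),
    gr0(bundle$te$chrom, bundle$te$start, bundle$te$end))
  unique(bundle$genes$transcript_id[S4Vectors::queryHits(h)])
}

#' Simulate the default study fixture
#'
#' Builds the default reference bundle, derives its cluster specifications,
#' and simulates one library per stage (BC, PGC, E11G, E14G, AT).
#'
#' @param seed master seed; bundle and per-sample seeds are derived from it.
#' @param n_reads total reads per library (piRNA reads plus contaminants).
#' @param noise contaminant depths, see [default_noise()].
#' @param stages stage labels to simulate.
#' @return list of class `pr_fixture`: `bundle`, `specs`, `samples` (named
#'   list of `pr_sim_sample`), `noise`, `seed`.
#' @export
simulate_fixture <- function(seed = 42, n_reads = 200000,
                             noise = default_noise(),
                             stages = c("BC", "PGC", "E11G", "E14G", "AT")) {
  seeds <- derive_seeds(seed, length(stages) + 1L)
  bundle <- build_reference(seed = seeds[1L])
  specs <- default_fixture_specs(bundle)
  n_pirna <- n_reads - sum(unlist(noise))
  if (n_pirna <= 0) stopf("n_reads must exceed the total contaminant count")
  samples <- lapply(seq_along(stages), function(i)
    simulate_sample(bundle, specs, stages[i], n_reads = n_pirna,
                    noise = noise, sample_id = stages[i],
                    seed = seeds[i + 1L]))
  names(samples) <- stages
  structure(list(bundle = bundle, specs = specs, samples = samples,
                 noise = noise, seed = seed), class = "pr_fixture")
}

#' Compare a candidate set against the simulation truth
#'
#' Sequence-level comparison (the generator guarantees class separability by
#' sequence): recall is the fraction of planted piRNA copies recovered as
#' candidates, precision the fraction of candidate copies that are planted
#' piRNAs.
#'
#' @param cands a `pr_candidates`.
#' @param truth the truth manifest of the matching `pr_sim_sample`.
#' @return list with `recall`, `precision`, `true_copies`,
#'   `planted_copies`, `candidate_copies`.
#' @export
evaluate_candidates <- function(cands, truth) {
  truth <- data.table::as.data.table(truth)
  pir_seqs <- truth[class %in% c("piRNA_TE", "piRNA_cluster"),
                    .(planted = .N), by = sequence]
  planted_total <- sum(pir_seqs$planted)
  cand <- data.table::as.data.table(cands$reads)[, .(sequence, copies)]
  m <- merge(cand, pir_seqs, by = "sequence", all.x = TRUE)
  true_copies <- sum(pmin(m$copies, m$planted), na.rm = TRUE)
  list(recall = if (planted_total > 0) true_copies / planted_total else NA_real_,
       precision = if (cands$denom > 0) true_copies / cands$denom else NA_real_,
       true_copies = true_copies, planted_copies = planted_total,
       candidate_copies = cands$denom)
}
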