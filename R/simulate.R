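#' The small-RNA 3' adaptor used by default
#'
#' Illumina TruSeq small-RNA 3' adaptor appended to every simulated read and
#' trimmed by the candidacy pipeline.
#' @return a character scalar.
#' @export
default_adaptor <- function() "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC"

#' Specify a planted piRNA cluster
#'
#' Describes one genomic locus that emits piRNA reads: its directionality
#' mode, relative emission weight per developmental stage, 5'-uracil
#' probability, ping-pong pair fraction, and read-length distribution.
#'
#' @param chrom,start,end locus coordinates (0-based half-open); the span must
#'   be at least 1 kb.
#' @param mode one of `"mono_plus"`, `"mono_minus"`, `"bidirectional"`
#'   (two divergent contiguous strand blocks split at the midpoint) or
#'   `"dual_strand"` (reads interleaved on both strands).
#' @param stage_weights named numeric vector of relative emission weights
#'   (>= 0), one entry per stage label.
#' @param n_reads cluster size factor; reads emitted for a stage are allocated
#'   multinomially with probability proportional to
#'   `n_reads * stage_weights[stage]`.
#' @param u1_prob probability that a non-ping-pong read starts with U (T).
#' @param pingpong_frac fraction of the cluster's reads emitted as ping-pong
#'   partner pairs (5' ends exactly 9 nt apart on opposite strands, A forced
#'   at position 10 of both members via anchor-site selection).
#' @param length_mean,length_sd read-length distribution (nt), clipped to
#'   24-34.
#' @param region_type annotation of what the locus overlaps ("TE", "genic" or
#'   "intergenic"); recorded in the truth manifest, not used for emission.
#' @param cluster_id optional identifier.
#' @return an object of class `pr_cluster_spec`.
#' @export
cluster_spec <- function(chrom, start, end, mode, stage_weights,
                         n_reads = 1000, u1_prob = 0.9, pingpong_frac = 0,
                         length_mean = 28, length_sd = 1.5,
                         region_type = "intergenic", cluster_id = NULL) {
  mode <- match.arg(mode, c("mono_plus", "mono_minus", "bidirectional",
                            "dual_strand"))
  if (end - start < 1000) stopf("cluster span must be >= 1000 nt")
  if (u1_prob < 0 || u1_prob > 1 || pingpong_frac < 0 || pingpong_frac > 1)
    stopf("u1_prob and pingpong_frac must lie in [0, 1]")
  if (is.null(names(stage_weights)) || any(stage_weights < 0))
    stopf("stage_weights must be a named non-negative vector")
  structure(list(chrom = chrom, start = as.integer(start),
                 end = as.integer(end), mode = mode,
                 stage_weights = stage_weights, n_reads = n_reads,
                 u1_prob = u1_prob, pingpong_frac = pingpong_frac,
                 length_mean = length_mean, length_sd = length_sd,
                 region_type = region_type,
                 cluster_id = cluster_id %||% sprintf("%s:%d-%d", chrom,
                                                      start, end)),
            class = "pr_cluster_spec")
}

## ---------------------------------------------------------------------------

## draw read coordinates for one cluster; chars is the chromosome's base vector
emit_cluster <- function(spec, n, chars, max_reject_iter = 30L) {
  if (n == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  role = character()))
  start <- spec$start; end <- spec$end
  lo <- start + 34L; hi <- end - 35L
  pos <- lo:hi                       # admissible 0-based 5' positions
  b <- chars[pos + 1L]
  mid <- as.integer(floor((start + end) / 2))

  seg_ok <- function(strand, p) switch(spec$mode,
    mono_plus = strand == "+", mono_minus = strand == "-",
    dual_strand = TRUE,
    bidirectional = if (strand == "-") p < mid else p >= mid)

  pool <- function(strand, u1) {
    want <- if (strand == "+") c("T", "A") else c("A", "T")
    keep <- if (u1) b == want[1L] else b != want[1L]
    p <- pos[keep]
    p[seg_ok(strand, p)]
  }
  anchor_pool <- function(strand) {
    if (strand == "+") {
      p <- pos[b == "T" & chars[pos + 10L] == "A"]
    } else {
      p <- pos[b == "A" & chars[pos - 8L] == "T"]
    }
    p[seg_ok(strand, p)]
  }
  draw_len <- function(k) as.integer(clip(round(rnorm(k, spec$length_mean,
                                                      spec$length_sd)), 24, 34))
  strand_of <- function(k) switch(spec$mode,
    mono_plus = rep("+", k), mono_minus = rep("-", k),
    sample(c("+", "-"), k, replace = TRUE))

  ## ping-pong pairs -------------------------------------------------------
  n_pair <- as.integer(floor(spec$pingpong_frac * n / 2))
  pp <- NULL
  if (n_pair > 0L) {
    ps <- strand_of(n_pair)
    rows <- vector("list", 2L)
    for (sgn in c("+", "-")) {
      k <- sum(ps == sgn)
      if (k == 0L) next
      ap <- anchor_pool(sgn)
      if (length(ap) == 0L)
        stopf("cluster %s has no ping-pong anchor sites on strand %s",
              spec$cluster_id, sgn)
      a <- ap[sample.int(length(ap), k, replace = TRUE)]
      L1 <- draw_len(k); L2 <- draw_len(k)
      if (sgn == "+") {
        prim <- data.table::data.table(start = a, end = a + L1, strand = "+")
        part <- data.table::data.table(start = a + 10L - L2, end = a + 10L,
                                       strand = "-")
      } else {
        prim <- data.table::data.table(start = a - L1 + 1L, end = a + 1L,
                                       strand = "-")
        part <- data.table::data.table(start = a - 9L, end = a - 9L + L2,
                                       strand = "+")
      }
      prim[, role := "pp_primary"]; part[, role := "pp_partner"]
      rows[[sgn]] <- rbind(prim, part)
    }
    pp <- data.table::rbindlist(rows)
  }

  ## background reads, kept clear of incidental exact-10-nt overlaps -------
  n_bg <- n - 2L * n_pair
  bg <- NULL
  if (n_bg > 0L) {
    st <- strand_of(n_bg)
    u1 <- runif(n_bg) < spec$u1_prob
    fp <- integer(n_bg)
    for (sgn in c("+", "-")) for (uu in c(TRUE, FALSE)) {
      sel <- st == sgn & u1 == uu
      if (!any(sel)) next
      pl <- pool(sgn, uu)
      if (length(pl) == 0L)
        stopf("cluster %s: empty position pool (strand %s)", spec$cluster_id,
              sgn)
      fp[sel] <- pl[sample.int(length(pl), sum(sel), replace = TRUE)]
    }
    pp_plus <- if (is.null(pp)) integer() else {
      dtp <- pp[strand == "+"]; dtp$start
    }
    pp_minus <- if (is.null(pp)) integer() else {
      dtm <- pp[strand == "-"]; dtm$end - 1L
    }
    for (it in seq_len(max_reject_iter)) {
      plus5 <- c(pp_plus, fp[st == "+"])
      minus5 <- c(pp_minus, fp[st == "-"])
      bad <- (st == "+" & (fp + 9L) %in% minus5) |
             (st == "-" & (fp - 9L) %in% plus5)
      if (!any(bad)) break
      for (sgn in c("+", "-")) for (uu in c(TRUE, FALSE)) {
        sel <- bad & st == sgn & u1 == uu
        if (!any(sel)) next
        pl <- pool(sgn, uu)
        fp[sel] <- pl[sample.int(length(pl), sum(sel), replace = TRUE)]
      }
    }
    L <- draw_len(n_bg)
    bg <- data.table::data.table(
      start = ifelse(st == "+", fp, fp - L + 1L),
      end = ifelse(st == "+", fp + L, fp + 1L),
      strand = st, role = "bg")
  }
  out <- data.table::rbindlist(list(pp, bg), use.names = TRUE)
  out[, chrom := spec$chrom]
  data.table::setcolorder(out, c("chrom", "start", "end", "strand", "role"))
  out[]
}

## ---------------------------------------------------------------------------

#' Simulate one stage's small-RNA library
#'
#' Emits piRNA reads from the given cluster specifications (allocated
#' multinomially by stage weight), ncRNA contaminant fragments drawn from the
#' bundle's rRNA/tRNA/miRNA loci, and uniform genomic degradation reads, then
#' appends the 3' adaptor. Every read is an exact substring of the genome
#' (strand-adjusted), and every read gets a truth-manifest record. Class
#' separability is enforced: degradation reads are redrawn until their
#' sequences match neither any ncRNA locus nor any planted piRNA sequence,
#' and miRNA fragments are redrawn if they collide with rRNA/tRNA sequences.
#'
#' @param bundle a `pr_bundle` from [build_reference()].
#' @param specs list of [cluster_spec()] objects; every spec must carry a
#'   weight for `stage`.
#' @param stage stage label of this library.
#' @param n_reads total number of piRNA reads to emit.
#' @param noise named list of contaminant read counts:
#'   `degradation`, `rrna`, `trna`, `mirna`, `pred_mirna`.
#' @param adaptor 3' adaptor appended to each read, or `NULL` for none.
#' @param sample_id sample identifier (defaults to the stage label).
#' @param seed integer seed.
#' @param max_reject_iter iteration cap for the collision-avoidance loops.
#' @return an object of class `pr_sim_sample`: list with `reads` (insert
#'   sequences, named [Biostrings::DNAStringSet]), `raw` (with adaptor),
#'   `truth` (data.table: read_id, class, chrom, start, end, strand, length,
#'   sequence, stage, source, role), `clusters` (planted-cluster registry
#'   with per-cluster emitted counts), `expected_profile` (region-type
#'   fractions over piRNA reads), `planted` (per-class copy counts and the
#'   planted pairable fraction), `stage`, `sample_id`.
#' @export
simulate_sample <- function(bundle, specs, stage, n_reads = 190000,
                            noise = default_noise(),
                            adaptor = default_adaptor(),
                            sample_id = stage, seed,
                            max_reject_iter = 30L) {
  if (missing(seed)) stopf("simulate_sample() requires an explicit 'seed'")
  if (inherits(specs, "pr_cluster_spec")) specs <- list(specs)
  chr_len <- Biostrings::width(bundle$genome)
  names(chr_len) <- names(bundle$genome)
  for (sp in specs) {
    if (!sp$chrom %in% names(chr_len) || sp$start < 0 ||
        sp$end > chr_len[[sp$chrom]])
      stopf("cluster spec %s lies outside the genome", sp$cluster_id)
    if (!stage %in% names(sp$stage_weights))
      stopf("unknown stage '%s': missing from stage_weights of %s", stage,
            sp$cluster_id)
    nc <- bundle$ncrna[bundle$ncrna$chrom == sp$chrom, ]
    if (nrow(nc) && any(nc$start < sp$end & nc$end > sp$start))
      stopf("cluster spec %s overlaps an ncRNA locus; separability guard",
            sp$cluster_id)
  }
  noise <- utils::modifyList(list(degradation = 0, rrna = 0, trna = 0,
                                  mirna = 0, pred_mirna = 0),
                             as.list(noise))

  with_seed(seed, {
    chars <- lapply(bundle$genome, function(s)
      strsplit(as.character(s), "", fixed = TRUE)[[1]])

    ## allocate piRNA reads over clusters
    w <- vapply(specs, function(sp)
      sp$stage_weights[[stage]] * sp$n_reads, numeric(1))
    counts <- if (n_reads > 0L && sum(w) > 0) {
      as.integer(rmultinom(1L, n_reads, prob = w))
    } else rep(0L, length(specs))

    reads <- vector("list", length(specs))
    for (i in seq_along(specs)) {
      r <- emit_cluster(specs[[i]], counts[i], chars[[specs[[i]]$chrom]],
                        max_reject_iter)
      if (nrow(r)) {
        r[, source := specs[[i]]$cluster_id]
        r[, class := if (specs[[i]]$region_type == "TE") "piRNA_TE"
                     else "piRNA_cluster"]
      }
      reads[[i]] <- r
    }
    reads <- data.table::rbindlist(reads, fill = TRUE)

    ## contaminant fragments from ncRNA loci
    frag_from <- function(loci, k, len_range, cls) {
      if (k == 0L || nrow(loci) == 0L) return(NULL)
      idx <- sample.int(nrow(loci), k, replace = TRUE)
      L <- sample(len_range[1]:len_range[2], k, replace = TRUE)
      L <- pmin(L, loci$end[idx] - loci$start[idx])
      off <- floor(runif(k) * (loci$end[idx] - loci$start[idx] - L + 1L))
      st <- loci$strand[idx]
      data.table::data.table(
        chrom = loci$chrom[idx],
        start = as.integer(ifelse(st == "+", loci$start[idx] + off,
                                  loci$end[idx] - off - L)),
        end = as.integer(ifelse(st == "+", loci$start[idx] + off + L,
                                loci$end[idx] - off)),
        strand = st, role = "contaminant", source = loci$ncrna_id[idx],
        class = cls)
    }
    nc <- bundle$ncrna
    cont <- data.table::rbindlist(list(
      frag_from(nc[nc$class == "rRNA", ], noise$rrna, c(24L, 34L), "rRNA_frag"),
      frag_from(nc[nc$class == "tRNA", ], noise$trna, c(24L, 34L), "tRNA_frag"),
      frag_from(nc[nc$class == "miRNA", ], noise$mirna, c(18L, 23L), "miRNA"),
      frag_from(nc[nc$class == "pred_miRNA", ], noise$pred_mirna,
                c(18L, 23L), "miRNA")), use.names = TRUE)

    all_reads <- data.table::rbindlist(list(reads, cont), use.names = TRUE,
                                       fill = TRUE)
    is_pred_mi <- function(dt) dt$class == "miRNA" &
      startsWith(dt$source, "pred_miRNA")

    ## pull sequences (strand-adjusted exact genome substrings)
    seq_of <- function(dt) {
      out <- character(nrow(dt))
      for (ch in unique(dt$chrom)) {
        ii <- which(dt$chrom == ch)
        ss <- Biostrings::extractAt(
          bundle$genome[[ch]], IRanges::IRanges(dt$start[ii] + 1L, dt$end[ii]))
        ss <- as.character(ss)
        neg <- dt$strand[ii] == "-"
        if (any(neg)) ss[neg] <- revcomp_chr(ss[neg])
        out[ii] <- ss
      }
      out
    }
    all_reads[, sequence := seq_of(all_reads)]

    ## separability guards ---------------------------------------------------
    nc_seqs <- bundle$ncrna$sequence
    pir <- all_reads$class %in% c("piRNA_TE", "piRNA_cluster")
    if (any(pir)) {
      uq <- unique(all_reads$sequence[pir])
      if (any(substring_hits(uq, nc_seqs)))
        stopf("collision guard: a planted piRNA sequence occurs inside an ncRNA locus")
    }
    ## miRNA fragments must be removable exactly at their own filter step:
    ## known-miRNA reads may not collide with rRNA/tRNA sequences, predicted
    ## ones additionally not with known precursors
    guard_frags <- function(sel, pool_class, against) {
      if (!any(sel) || !length(against)) return(invisible(NULL))
      for (it in seq_len(max_reject_iter)) {
        bad <- which(sel)[substring_hits(all_reads$sequence[sel], against)]
        if (!length(bad)) break
        redo <- frag_from(nc[nc$class %in% pool_class, ], length(bad),
                          c(18L, 23L), "miRNA")
        redo[, sequence := seq_of(redo)]
        all_reads[bad, c("chrom", "start", "end", "strand", "source",
                         "sequence") :=
                    redo[, .(chrom, start, end, strand, source, sequence)]]
      }
      invisible(NULL)
    }
    rt_seqs <- nc_seqs[bundle$ncrna$class %in% c("rRNA", "tRNA")]
    known_mi_seqs <- nc_seqs[bundle$ncrna$class == "miRNA"]
    guard_frags(all_reads$class == "miRNA" & !is_pred_mi(all_reads),
                "miRNA", rt_seqs)
    guard_frags(is_pred_mi(all_reads), "pred_miRNA",
                c(rt_seqs, known_mi_seqs))

    ## degradation reads: uniform genomic, guarded against class collisions
    deg <- NULL
    if (noise$degradation > 0L) {
      pir_set <- unique(all_reads$sequence[pir])
      pir_set <- c(pir_set, revcomp_chr(pir_set))
      draw_deg <- function(k) {
        ch <- sample(names(chr_len), k, replace = TRUE, prob = chr_len)
        L <- sample(24:34, k, replace = TRUE)
        s0 <- as.integer(floor(runif(k) * (chr_len[ch] - L)))
        data.table::data.table(chrom = ch, start = s0, end = s0 + L,
                               strand = sample(c("+", "-"), k, replace = TRUE),
                               role = "degradation", source = "genome",
                               class = "degradation")
      }
      deg <- draw_deg(noise$degradation)
      deg[, sequence := seq_of(deg)]
      for (it in seq_len(max_reject_iter)) {
        bad <- which(substring_hits(deg$sequence, nc_seqs) |
                       deg$sequence %in% pir_set)
        if (!length(bad)) break
        redo <- draw_deg(length(bad))
        redo[, sequence := seq_of(redo)]
        deg[bad, (names(deg)) := redo]
      }
    }
    all_reads <- data.table::rbindlist(list(all_reads, deg),
                                       use.names = TRUE, fill = TRUE)
    all_reads[, read_id := sprintf("R%07d", seq_len(.N))]
    all_reads[, `:=`(length = end - start, stage = stage)]
    data.table::setcolorder(all_reads, c("read_id", "class", "chrom", "start",
                                         "end", "strand", "length", "sequence",
                                         "stage", "source", "role"))

    inserts <- Biostrings::DNAStringSet(all_reads$sequence)
    names(inserts) <- all_reads$read_id
    raw <- if (is.null(adaptor)) inserts else {
      x <- Biostrings::xscat(inserts, Biostrings::DNAString(adaptor))
      names(x) <- all_reads$read_id
      x
    }

    pir_dt <- all_reads[class %in% c("piRNA_TE", "piRNA_cluster")]
    expected_profile <- if (nrow(pir_dt)) {
      rt <- vapply(specs, function(sp) sp$region_type, character(1))
      names(rt) <- vapply(specs, function(sp) sp$cluster_id, character(1))
      tab <- pir_dt[, .N, by = .(region = rt[source])]
      tab[, fraction := N / sum(N)][]
    } else data.table::data.table(region = character(), N = integer(),
                                  fraction = numeric())

    registry <- data.table::rbindlist(lapply(seq_along(specs), function(i) {
      sp <- specs[[i]]
      data.table::data.table(cluster_id = sp$cluster_id, chrom = sp$chrom,
                             start = sp$start, end = sp$end, mode = sp$mode,
                             region_type = sp$region_type,
                             n_emitted = counts[i])
    }))

    structure(list(
      reads = inserts, raw = raw, truth = all_reads,
      clusters = registry, expected_profile = expected_profile,
      planted = list(
        class_counts = all_reads[, .N, by = class],
        known_mirna = sum(all_reads$class == "miRNA" &
                            !is_pred_mi(all_reads)),
        pred_mirna = sum(is_pred_mi(all_reads)),
        pairable_frac = if (nrow(pir_dt))
          sum(pir_dt$role %in% c("pp_primary", "pp_partner")) / nrow(pir_dt)
        else 0),
      stage = stage, sample_id = sample_id, seed = seed),
      class = "pr_sim_sample")
  })
}

#' @export
print.pr_sim_sample <- function(x, ...) {
  cat(sprintf("pr_sim_sample '%s' (stage %s): %d reads (%d piRNA)\n",
              x$sample_id, x$stage, length(x$reads),
              sum(x$truth$class %in% c("piRNA_TE", "piRNA_cluster"))))
  invisible(x)
}
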