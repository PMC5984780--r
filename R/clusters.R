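#' Classify the directionality mode of a cluster's reads
#'
#' Mono-directional if >= 90% of copies lie on one strand. Otherwise reads
#' are ordered by 5' position and the best single split point into two
#' contiguous opposite-strand blocks (either orientation) is sought;
#' bidirectional if at most 10% of copies violate the best split, dual-strand
#' otherwise.
#'
#' @param reads MappedRead data.table of the cluster's members.
#' @param mono_frac strand-copy fraction declaring mono-directionality.
#' @param max_violation tolerated copy fraction violating the best split.
#' @return one of "mono_plus", "mono_minus", "bidirectional", "dual_strand".
#' @export
classify_mode <- function(reads, mono_frac = 0.9, max_violation = 0.1) {
  cp <- reads$copies
  total <- sum(cp)
  plus <- sum(cp[reads$strand == "+"])
  if (plus / total >= mono_frac) return("mono_plus")
  if ((total - plus) / total >= mono_frac) return("mono_minus")
  ord <- order(five_prime(reads), reads$start)
  st <- reads$strand[ord]; cpo <- cp[ord]
  cum_plus <- cumsum(ifelse(st == "+", cpo, 0))
  cum_minus <- cumsum(ifelse(st == "-", cpo, 0))
  tp <- cum_plus[length(cpo)]; tm <- cum_minus[length(cpo)]
  k <- c(0L, seq_along(cpo))
  pre_plus <- c(0, cum_plus); pre_minus <- c(0, cum_minus)
  ## orientation minus-block then plus-block: violations = plus before split
  ## + minus after split; mirrored for the other orientation
  viol_mp <- pre_plus + (tm - pre_minus)
  viol_pm <- pre_minus + (tp - pre_plus)
  if (min(viol_mp, viol_pm) / total <= max_violation) "bidirectional"
  else "dual_strand"
}

#' Detect piRNA clusters in one sample
#'
#' Deterministic density detector: reads are ordered by 5' position per
#' chromosome; runs with consecutive 5' gaps <= `max_gap` form candidate
#' loci, whose boundaries are the minimum start to maximum end of member
#' reads. A locus is kept iff it satisfies every threshold: >= `min_distinct`
#' distinct sequences, >= `min_copies` copies, density >= `min_density`
#' copies/kb, first-base U fraction >= `min_u1`, and span >= `min_len`.
#'
#' @param cands a `pr_candidates`.
#' @param max_gap maximum 5'-to-5' gap (nt) within a locus.
#' @param min_distinct minimum distinct sequences.
#' @param min_copies minimum copy count.
#' @param min_density minimum copies per kb.
#' @param min_u1 minimum copy-weighted fraction of reads starting with U (T).
#' @param min_len minimum locus span (nt).
#' @return data.table of clusters: sample_id, chrom, start, end, mode,
#'   n_copies, n_distinct, u1_fraction, density.
#' @export
detect_clusters <- function(cands, max_gap = 5000, min_distinct = 5,
                            min_copies = 10, min_density = 10, min_u1 = 0.5,
                            min_len = 1000) {
  empty <- data.table::data.table(
    sample_id = character(), chrom = character(), start = integer(),
    end = integer(), mode = character(), n_copies = integer(),
    n_distinct = integer(), u1_fraction = numeric(), density = numeric())
  reads <- data.table::as.data.table(cands$reads)
  if (nrow(reads) == 0L) return(empty)
  reads[, fp := five_prime(reads)]
  data.table::setorder(reads, chrom, fp, start)
  reads[, run_id := cumsum(c(TRUE, diff(fp) > max_gap)), by = chrom]
  out <- reads[, {
    u1 <- sum(copies[substr(sequence, 1L, 1L) == "T"]) / sum(copies)
    .(start = min(start), end = max(end), n_copies = sum(copies),
      n_distinct = data.table::uniqueN(sequence), u1_fraction = u1,
      mode = classify_mode(.SD))
  }, by = .(chrom, run_id)]
  out[, density := n_copies / ((end - start) / 1000)]
  out <- out[n_distinct >= min_distinct & n_copies >= min_copies &
               density >= min_density & u1_fraction >= min_u1 &
               (end - start) >= min_len]
  out[, `:=`(sample_id = cands$sample_id, run_id = NULL)]
  data.table::setcolorder(out, c("sample_id", "chrom", "start", "end", "mode",
                                 "n_copies", "n_distinct", "u1_fraction",
                                 "density"))
  data.table::setorder(out, chrom, start)
  out[]
}

#' Merge per-sample clusters into a cross-sample registry
#'
#' Same-chromosome clusters overlapping by >= 1 bp (strand-agnostic) are
#' unioned transitively; merged coordinates are the union span. The result
#' is independent of input order and idempotent, with pairwise-disjoint
#' intervals per chromosome.
#'
#' @param cluster_tables list (or single data.table) of per-sample cluster
#'   tables from [detect_clusters()].
#' @return list of class `pr_registry`: `clusters` (cluster_id, chrom,
#'   start, end) and `members` (cluster_id x member sample clusters).
#' @export
merge_clusters <- function(cluster_tables) {
  if (data.table::is.data.table(cluster_tables))
    cluster_tables <- list(cluster_tables)
  all_cl <- data.table::rbindlist(cluster_tables, use.names = TRUE,
                                  fill = TRUE)
  if (nrow(all_cl) == 0L)
    return(structure(list(
      clusters = data.table::data.table(cluster_id = character(),
                                        chrom = character(), start = integer(),
                                        end = integer()),
      members = data.table::data.table()), class = "pr_registry"))
  gr <- gr0(all_cl$chrom, all_cl$start, all_cl$end)
  merged <- IRanges::reduce(gr, ignore.strand = TRUE)
  ord <- order(as.character(GenomicRanges::seqnames(merged)),
               IRanges::start(merged), method = "radix")
  merged <- merged[ord]
  reg <- data.table::data.table(
    cluster_id = sprintf("piRC_%04d", seq_along(merged)),
    chrom = as.character(GenomicRanges::seqnames(merged)),
    start = IRanges::start(merged) - 1L, end = IRanges::end(merged))
  h <- GenomicRanges::findOverlaps(gr, merged)
  members <- data.table::data.table(
    cluster_id = reg$cluster_id[S4Vectors::subjectHits(h)],
    all_cl[S4Vectors::queryHits(h)])
  data.table::setorder(members, cluster_id, sample_id, chrom, start)
  structure(list(clusters = reg, members = members), class = "pr_registry")
}

#' @export
print.pr_registry <- function(x, ...) {
  cat(sprintf("pr_registry: %d merged clusters from %d member clusters\n",
              nrow(x$clusters), nrow(x$members)))
  invisible(x)
}

#' Extend merged clusters over expressed overlapping transcripts
#'
#' Iterates to a fixpoint: whenever a cluster overlaps a transcript whose
#' FPKM is >= `min_fpkm` in at least one RNA-seq dataset, the cluster grows
#' to cover the transcript span, then newly overlapped transcripts are
#' re-checked. Boundaries only grow; clusters that come to overlap after
#' extension are re-merged. With `samples` supplied, the copies per sample
#' assignable to clusters before vs after extension are recorded in
#' `clusterable_gain`.
#'
#' @param registry a `pr_registry` from [merge_clusters()].
#' @param genes transcript table (transcript_id, chrom, start, end).
#' @param fpkm FPKM table (transcript_id, dataset, fpkm).
#' @param min_fpkm expression gate (default 1).
#' @param samples optional named list of `pr_candidates` for the
#'   clusterable-gain audit.
#' @param max_iter iteration cap (growth is monotone and bounded, so this is
#'   a safety net).
#' @return a `pr_registry` with extended coordinates; attributes
#'   `extended_from` (pre-extension registry) and `clusterable_gain`.
#' @export
extend_by_transcripts <- function(registry, genes, fpkm, min_fpkm = 1,
                                  samples = NULL, max_iter = 50) {
  genes <- data.table::as.data.table(genes)
  fpkm <- data.table::as.data.table(fpkm)
  expressed <- fpkm[, .(max_fpkm = max(fpkm)), by = transcript_id][
    max_fpkm >= min_fpkm, transcript_id]
  tx <- genes[transcript_id %in% expressed]
  cl <- data.table::copy(registry$clusters)
  if (nrow(cl) && nrow(tx)) {
    tx_gr <- gr0(tx$chrom, tx$start, tx$end)
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter)
        stopf("transcript extension did not reach a fixpoint in %d iterations",
              max_iter)
      h <- GenomicRanges::findOverlaps(gr0(cl$chrom, cl$start, cl$end), tx_gr)
      if (!length(h)) break
      q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
      upd <- data.table::data.table(q = q, ts = tx$start[s], te = tx$end[s])[
        , .(new_start = min(ts), new_end = max(te)), by = q]
      ns <- pmin(cl$start[upd$q], upd$new_start)
      ne <- pmax(cl$end[upd$q], upd$new_end)
      changed <- ns != cl$start[upd$q] | ne != cl$end[upd$q]
      if (!any(changed)) break
      cl[upd$q, `:=`(start = ns, end = ne)]
    }
  }
  ## re-merge clusters that grew into one another, keep member provenance
  grown <- merge_clusters(list(cl[, .(sample_id = cluster_id, chrom, start,
                                      end)]))
  out_clusters <- grown$clusters
  remap <- grown$members[, .(new_id = cluster_id, cluster_id = sample_id)]
  members <- merge(registry$members, remap, by = "cluster_id", sort = FALSE)
  members[, cluster_id := new_id][, new_id := NULL]
  out <- structure(list(clusters = out_clusters, members = members),
                   class = "pr_registry")
  attr(out, "extended_from") <- registry$clusters
  if (!is.null(samples)) {
    gain <- data.table::rbindlist(lapply(names(samples), function(nm) {
      cd <- samples[[nm]]
      before <- sum(assign_to_clusters(cd, registry)$copies, na.rm = TRUE)
      after <- sum(assign_to_clusters(cd, out)$copies, na.rm = TRUE)
      data.table::data.table(sample_id = nm, clusterable_before = before,
                             clusterable_after = after)
    }))
    attr(out, "clusterable_gain") <- gain
  }
  out
}

## copies of a candidate set assignable to registry clusters (5'-position
## ownership, half-open)
assign_to_clusters <- function(cands, registry) {
  reads <- cands$reads
  if (nrow(reads) == 0L || nrow(registry$clusters) == 0L)
    return(data.table::data.table(cluster_id = character(), copies = integer()))
  fp <- five_prime(reads)
  fp_gr <- gr0(reads$chrom, fp, fp + 1L)
  cl_gr <- gr0(registry$clusters$chrom, registry$clusters$start,
               registry$clusters$end)
  h <- GenomicRanges::findOverlaps(fp_gr, cl_gr)
  data.table::data.table(
    cluster_id = registry$clusters$cluster_id[S4Vectors::subjectHits(h)],
    copies = reads$copies[S4Vectors::queryHits(h)])[
      , .(copies = sum(copies)), by = cluster_id]
}

#' Quantify cluster expression as piRPKM
#'
#' A read belongs to a cluster iff its 5' position lies within the cluster
#' (half-open). piRPKM = copies / (cluster length in kb x sample candidate
#' millions); multiplying every copy count in a sample by a constant leaves
#' piRPKM unchanged. Stage values average the stage's member samples.
#'
#' @param registry a `pr_registry`.
#' @param samples named list of `pr_candidates`.
#' @param stage_groups named character vector mapping a sample's stage label
#'   to its stage group (e.g. E11G/E14G to EG).
#' @return list of class `pr_stage_matrix`: `sample_matrix` (clusters x
#'   samples), `stage_matrix` (clusters x stage groups), `cluster_kb`,
#'   `stage_of` (sample to group map).
#' @export
quantify_pirpkm <- function(registry, samples,
                            stage_groups = c(BC = "BC", PGC = "PGC",
                                             E11G = "EG", E14G = "EG",
                                             AT = "AT")) {
  cl <- registry$clusters
  kb <- (cl$end - cl$start) / 1000
  sm <- matrix(0, nrow(cl), length(samples),
               dimnames = list(cl$cluster_id, names(samples)))
  stage_of <- character(length(samples)); names(stage_of) <- names(samples)
  for (nm in names(samples)) {
    cd <- samples[[nm]]
    if (cd$denom == 0) stopf("sample '%s' has denom = 0; piRPKM undefined", nm)
    asg <- assign_to_clusters(cd, registry)
    v <- setNames(rep(0, nrow(cl)), cl$cluster_id)
    v[asg$cluster_id] <- asg$copies
    sm[, nm] <- v / kb / (cd$denom / 1e6)
    stg <- cd$stage
    stage_of[nm] <- if (stg %in% names(stage_groups)) stage_groups[[stg]] else stg
  }
  groups <- unique(stage_of)
  gm <- sapply(groups, function(g)
    rowMeans(sm[, stage_of == g, drop = FALSE]))
  gm <- matrix(gm, nrow = nrow(cl), dimnames = list(cl$cluster_id, groups))
  structure(list(sample_matrix = sm, stage_matrix = gm, cluster_kb = kb,
                 stage_of = stage_of), class = "pr_stage_matrix")
}

#' Classify stage enrichment of merged clusters
#'
#' A cluster is enriched in stage s iff its piRPKM there is >= `min_expr`
#' and >= `fold` times the second-highest stage; clusters below `min_expr`
#' everywhere are `not_expressed`; a top stage failing the fold test (ties
#' included) gives `shared`.
#'
#' @param stage_matrix clusters x stages numeric matrix (or a
#'   `pr_stage_matrix`).
#' @param min_expr expression cutoff in piRPKM.
#' @param fold required fold over the second-highest stage.
#' @return data.table with cluster_id, label (e.g. "BC-piRC", "shared",
#'   "not_expressed"), top_stage, top_value, second_value.
#' @export
classify_stage_enrichment <- function(stage_matrix, min_expr = 0.1,
                                      fold = 1.5) {
  m <- if (inherits(stage_matrix, "pr_stage_matrix"))
    stage_matrix$stage_matrix else as.matrix(stage_matrix)
  if (ncol(m) < 2L) stopf("stage enrichment needs >= 2 stages")
  stages <- colnames(m)
  top_i <- max.col(m, ties.method = "first")
  top <- m[cbind(seq_len(nrow(m)), top_i)]
  m2 <- m; m2[cbind(seq_len(nrow(m)), top_i)] <- -Inf
  second <- apply(m2, 1L, max)
  label <- ifelse(top < min_expr, "not_expressed",
                  ifelse(top >= fold * second,
                         paste0(stages[top_i], "-piRC"), "shared"))
  data.table::data.table(cluster_id = rownames(m) %||%
                           sprintf("piRC_%04d", seq_len(nrow(m))),
                         label = label, top_stage = stages[top_i],
                         top_value = top, second_value = second)
}

#' Classical MDS embedding of samples by cluster expression
#'
#' Torgerson MDS on Euclidean distances between samples in
#' log10(piRPKM + 0.01) space, reporting per-dimension eigenvalue fractions
#' (computed over the positive eigenvalues).
#'
#' @param sample_matrix clusters x samples matrix (or `pr_stage_matrix`).
#' @param k embedding dimensionality.
#' @param pseudo offset inside the log.
#' @return list with `points` (samples x k), `eig`, `eig_fraction`.
#' @export
mds_embedding <- function(sample_matrix, k = 2, pseudo = 0.01) {
  m <- if (inherits(sample_matrix, "pr_stage_matrix"))
    sample_matrix$sample_matrix else as.matrix(sample_matrix)
  if (ncol(m) < 3L) stopf("MDS embedding needs >= 3 samples")
  x <- t(log10(m + pseudo))
  fit <- stats::cmdscale(stats::dist(x), k = k, eig = TRUE)
  pos <- pmax(fit$eig, 0)
  frac <- if (sum(pos) > 0) pos / sum(pos) else pos
  pts <- fit$points
  if (ncol(pts) < k) {  # degenerate configurations may span fewer dimensions
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  rownames(pts) <- colnames(m)
  list(points = pts, eig = fit$eig, eig_fraction = frac)
}

#' Flag syntenically conserved clusters between species
#'
#' An anchor is a pair of flanking genes given per species; it is conserved
#' iff every species has at least one cluster lying wholly inside the open
#' interval between its two anchor genes (strict containment: the cluster
#' must not touch either gene span).
#'
#' @param anchors list of anchors; each anchor is a list with `name` and
#'   `species`, the latter a named list of
#'   `list(chrom, geneA = c(start, end), geneB = c(start, end))` with geneA
#'   before geneB.
#' @param clusters_by_species named list of cluster tables (chrom, start,
#'   end), one per species.
#' @return data.table with anchor, one logical column per species, and
#'   `conserved`.
#' @export
synteny_check <- function(anchors, clusters_by_species) {
  rows <- lapply(anchors, function(a) {
    flags <- vapply(names(a$species), function(sp) {
      loc <- a$species[[sp]]
      if (loc$geneA[2] > loc$geneB[1])
        stopf("anchor '%s': genes overlap or are out of order in %s",
              a$name, sp)
      cl <- clusters_by_species[[sp]]
      if (is.null(cl) || nrow(cl) == 0L) return(FALSE)
      any(cl$chrom == loc$chrom & cl$start >= loc$geneA[2] &
            cl$end <= loc$geneB[1])
    }, logical(1))
    out <- data.table::as.data.table(as.list(flags))
    out[, `:=`(anchor = a$name, conserved = all(flags))]
    out
  })
  out <- data.table::rbindlist(rows, use.names = TRUE, fill = TRUE)
  data.table::setcolorder(out, c("anchor",
                                 setdiff(names(out), c("anchor", "conserved")),
                                 "conserved"))
  out[]
}
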