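#' Blacklist sequence sets of a reference bundle
#'
#' @param bundle a `pr_bundle`.
#' @return list with `rrna_trna`, `mirna`, `pred_mirna` (DNAStringSets).
#' @export
bundle_blacklists <- function(bundle) {
  nc <- bundle$ncrna
  as_set <- function(sel) {
    x <- Biostrings::DNAStringSet(nc$sequence[sel])
    names(x) <- nc$ncrna_id[sel]
    x
  }
  list(rrna_trna = as_set(nc$class %in% c("rRNA", "tRNA")),
       mirna = as_set(nc$class == "miRNA"),
       pred_mirna = as_set(nc$class == "pred_miRNA"))
}

#' Run the full stage-resolved piRNA analysis
#'
#' Applies the candidacy cascade to every sample, computes per-sample piRNA
#' signatures (length spectrum, positional composition, overlap spectrum,
#' ping-pong subset composition and z-score) and annotation profiles
#' (genomic association, per-TE-family sense/antisense piRPM), detects
#' clusters per sample, merges them across samples, extends boundaries over
#' expressed transcripts, quantifies piRPKM, classifies stage enrichment,
#' embeds samples by MDS, and selects piRNA-associated transcripts
#' (top targets, stage union, E11G-vs-E14G differential association,
#' biotype breakdown). With `out_dir` given, every table is written as
#' TSV/BED with deterministic formatting.
#'
#' @param fixture a `pr_fixture` from [simulate_fixture()], or a list with
#'   `bundle` and `samples` where each sample has `raw` reads and a `stage`.
#' @param out_dir optional output directory.
#' @param cluster_params named list overriding [detect_clusters()] defaults.
#' @param target_stages two stages compared for targets (default E11G/E14G).
#' @return a list of class `pr_results` with elements `candidates`,
#'   `reports`, `signatures`, `profiles`, `clusters`, `registry`,
#'   `extended`, `pirpkm`, `enrichment`, `mds`, `targets`.
#' @export
run_pipeline <- function(fixture, out_dir = NULL, cluster_params = list(),
                         target_stages = c("E11G", "E14G")) {
  bundle <- fixture$bundle
  index <- build_exact_index(bundle$genome)
  blk <- bundle_blacklists(bundle)
  findex <- build_feature_index(bundle)

  candidates <- list(); reports <- list(); signatures <- list()
  profiles <- list(); per_sample_clusters <- list()
  for (nm in names(fixture$samples)) {
    s <- fixture$samples[[nm]]
    cc <- run_candidacy(s$raw, index, blk, sample_id = nm, stage = s$stage)
    candidates[[nm]] <- cc$candidates
    reports[[nm]] <- cc$report
    spec_len <- length_spectrum(cc$candidates)
    comp <- positional_composition(cc$candidates)
    ov <- overlap_spectrum(cc$candidates)
    signatures[[nm]] <- list(
      length_spectrum = spec_len, composition = comp, overlap_spectrum = ov,
      pingpong_composition = pingpong_subset_composition(cc$candidates),
      pingpong_z = pingpong_enrichment(ov))
    profiles[[nm]] <- list(
      association = association_profile(cc$candidates, findex),
      te_family = te_family_profile(cc$candidates, findex))
    per_sample_clusters[[nm]] <- do.call(
      detect_clusters, c(list(cc$candidates), cluster_params))
  }

  registry <- merge_clusters(per_sample_clusters)
  extended <- extend_by_transcripts(registry, bundle$genes, bundle$fpkm,
                                    samples = candidates)
  pirpkm <- quantify_pirpkm(extended, candidates)
  enrichment <- classify_stage_enrichment(pirpkm)
  mds <- if (length(candidates) >= 3L) mds_embedding(pirpkm) else NULL

  targets <- NULL
  if (all(target_stages %in% names(candidates))) {
    assoc <- lapply(target_stages, function(st)
      transcript_association(candidates[[st]], bundle$genes, bundle$te))
    names(assoc) <- target_stages
    tops <- lapply(assoc, select_top_targets)
    uni <- stage_union(tops)
    diff <- differential_association(assoc[[1L]], assoc[[2L]])
    targets <- list(association = assoc, top = tops, union = uni,
                    differential = diff,
                    biotypes = biotype_breakdown(diff$transcript_id,
                                                 bundle$genes))
  }

  res <- structure(list(
    candidates = candidates, reports = reports, signatures = signatures,
    profiles = profiles, clusters = per_sample_clusters, registry = registry,
    extended = extended, pirpkm = pirpkm, enrichment = enrichment, mds = mds,
    targets = targets), class = "pr_results")
  if (!is.null(out_dir)) write_results(res, out_dir)
  res
}

#' Write pipeline results to disk
#'
#' @param res a `pr_results`.
#' @param out_dir output directory.
#' @return invisibly, `out_dir`.
#' @export
write_results <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  comp_dt <- function(cmp) {
    if (is.null(cmp$freq))
      return(data.table::data.table(position = integer(), base = character(),
                                    frequency = numeric(),
                                    enrichment = numeric()))
    dt <- data.table::as.data.table(as.table(cmp$freq))
    data.table::setnames(dt, c("base", "position", "frequency"))
    en <- data.table::as.data.table(as.table(cmp$enrichment))
    dt[, enrichment := en$N]
    dt[, position := as.integer(as.character(position))]
    data.table::setorder(dt, position, base)
    dt
  }
  for (nm in names(res$candidates)) {
    d <- file.path(out_dir, "samples", nm)
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    cd <- res$candidates[[nm]]
    write_bed6(data.table::data.table(
      chrom = cd$reads$chrom, start = cd$reads$start, end = cd$reads$end,
      name = cd$reads$read_id,
      score = cd$reads$copies, strand = cd$reads$strand),
      file.path(d, "candidates.bed"))
    write_tsv(cd$reads, file.path(d, "candidates.tsv"))
    write_tsv(res$reports[[nm]], file.path(d, "filter_report.tsv"))
    sg <- res$signatures[[nm]]
    write_tsv(sg$length_spectrum, file.path(d, "length_spectrum.tsv"))
    write_tsv(comp_dt(sg$composition), file.path(d, "composition.tsv"))
    write_tsv(sg$overlap_spectrum, file.path(d, "overlap_spectrum.tsv"))
    write_tsv(comp_dt(sg$pingpong_composition),
              file.path(d, "pingpong_composition.tsv"))
    write_tsv(res$profiles[[nm]]$association,
              file.path(d, "association_profile.tsv"))
    write_tsv(res$profiles[[nm]]$te_family,
              file.path(d, "te_family_profile.tsv"))
    cl <- res$clusters[[nm]]
    write_bed6(data.table::data.table(
      chrom = cl$chrom, start = cl$start, end = cl$end, name = cl$mode,
      score = cl$n_copies, strand = "."), file.path(d, "clusters.bed"))
  }
  write_tsv(res$registry$clusters, file.path(out_dir, "merged_clusters.tsv"))
  write_tsv(res$extended$clusters, file.path(out_dir, "extended_clusters.tsv"))
  gain <- attr(res$extended, "clusterable_gain")
  if (!is.null(gain)) write_tsv(gain, file.path(out_dir,
                                                "clusterable_gain.tsv"))
  sm <- data.table::as.data.table(res$pirpkm$sample_matrix,
                                  keep.rownames = "cluster_id")
  write_tsv(sm, file.path(out_dir, "sample_pirpkm.tsv"))
  gm <- data.table::as.data.table(res$pirpkm$stage_matrix,
                                  keep.rownames = "cluster_id")
  write_tsv(gm, file.path(out_dir, "stage_pirpkm.tsv"))
  write_tsv(res$enrichment, file.path(out_dir, "stage_enrichment.tsv"))
  if (!is.null(res$mds)) {
    pts <- data.table::as.data.table(res$mds$points,
                                     keep.rownames = "sample_id")
    write_tsv(pts, file.path(out_dir, "mds_points.tsv"))
    write_tsv(data.table::data.table(dimension = seq_along(res$mds$eig),
                                     eigenvalue = res$mds$eig,
                                     fraction = res$mds$eig_fraction),
              file.path(out_dir, "mds_eigenvalues.tsv"))
  }
  if (!is.null(res$targets)) {
    for (st in names(res$targets$association))
      write_tsv(res$targets$association[[st]],
                file.path(out_dir, sprintf("transcript_association_%s.tsv",
                                           st)))
    for (st in names(res$targets$top))
      write_tsv(res$targets$top[[st]],
                file.path(out_dir, sprintf("top_targets_%s.tsv", st)))
    write_tsv(res$targets$union, file.path(out_dir, "target_union.tsv"))
    write_tsv(res$targets$differential,
              file.path(out_dir, "differential_association.tsv"))
    write_tsv(res$targets$biotypes, file.path(out_dir,
                                              "target_biotypes.tsv"))
  }
  invisible(out_dir)
}

#' Fraction of candidate copies assignable to detected clusters
#'
#' @param res a `pr_results`.
#' @param registry which registry to assign against (`"extended"` or
#'   `"merged"`).
#' @return named numeric vector, one fraction per sample.
#' @export
clustered_fraction <- function(res, registry = c("extended", "merged")) {
  registry <- match.arg(registry)
  reg <- if (registry == "extended") res$extended else res$registry
  vapply(res$candidates, function(cd) {
    if (cd$denom == 0) return(NA_real_)
    sum(assign_to_clusters(cd, reg)$copies) / cd$denom
  }, numeric(1))
}
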