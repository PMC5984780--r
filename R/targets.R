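#' Associate piRNA candidates with transcripts
#'
#' A read associates with a transcript iff its interval overlaps the
#' transcript's genomic span by >= 1 bp (introns included). Reports
#' copy-weighted sense/antisense/total piRPM per transcript (orientation is
#' read strand vs transcript strand), the unique-mapper fraction (share of
#' total copies from reads with a single exact genomic placement), and the
#' TE-embedded fraction (share of total copies from reads overlapping TE
#' copies that intersect the transcript span).
#'
#' @param cands a `pr_candidates`.
#' @param genes transcript table (transcript_id, chrom, start, end, strand,
#'   biotype).
#' @param te optional TE table (chrom, start, end) for the TE-embedded audit.
#' @return data.table: transcript_id, sense_pirpm, antisense_pirpm,
#'   total_pirpm, unique_fraction, te_fraction, biotype.
#' @export
transcript_association <- function(cands, genes, te = NULL) {
  if (cands$denom == 0) stopf("empty candidate set (denom = 0)")
  genes <- data.table::as.data.table(genes)
  reads <- cands$reads
  empty <- data.table::data.table(
    transcript_id = character(), sense_pirpm = numeric(),
    antisense_pirpm = numeric(), total_pirpm = numeric(),
    unique_fraction = numeric(), te_fraction = numeric(),
    biotype = character())
  if (nrow(reads) == 0L || nrow(genes) == 0L) return(empty)
  rgr <- gr0(reads$chrom, reads$start, reads$end)
  tgr <- gr0(genes$chrom, genes$start, genes$end)
  h <- GenomicRanges::findOverlaps(rgr, tgr)
  if (!length(h)) return(empty)
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)

  te_hit <- rep(FALSE, length(q))
  if (!is.null(te) && nrow(te)) {
    te <- data.table::as.data.table(te)
    te_gr <- gr0(te$chrom, te$start, te$end)
    ## TE copies embedded in each transcript: TE-transcript intersections
    th <- GenomicRanges::findOverlaps(te_gr, tgr)
    if (length(th)) {
      emb <- GenomicRanges::pintersect(te_gr[S4Vectors::queryHits(th)],
                                       tgr[S4Vectors::subjectHits(th)])
      emb_tx <- S4Vectors::subjectHits(th)
      ## read-assoc pair (q, s) is TE-embedded if the read overlaps an
      ## embedded TE segment of transcript s
      rh <- GenomicRanges::findOverlaps(rgr, emb)
      if (length(rh)) {
        key_pairs <- paste(q, s)
        key_hits <- unique(paste(S4Vectors::queryHits(rh),
                                 emb_tx[S4Vectors::subjectHits(rh)]))
        te_hit <- key_pairs %in% key_hits
      }
    }
  }
  dt <- data.table::data.table(
    tx = genes$transcript_id[s],
    copies = reads$copies[q],
    sense = reads$strand[q] == genes$strand[s],
    unique_ = reads$n_hits[q] == 1L,
    te_emb = te_hit)
  out <- dt[, .(
    sense_pirpm = sum(copies[sense]) / cands$denom * 1e6,
    antisense_pirpm = sum(copies[!sense]) / cands$denom * 1e6,
    unique_fraction = sum(copies[unique_]) / sum(copies),
    te_fraction = sum(copies[te_emb]) / sum(copies)), by = .(transcript_id = tx)]
  out[, total_pirpm := sense_pirpm + antisense_pirpm]
  out <- merge(out, genes[, .(transcript_id, biotype)], by = "transcript_id",
               sort = TRUE)
  data.table::setcolorder(out, c("transcript_id", "sense_pirpm",
                                 "antisense_pirpm", "total_pirpm",
                                 "unique_fraction", "te_fraction", "biotype"))
  out[]
}

#' Select the top piRNA-associated transcripts
#'
#' Transcripts are ranked by total piRPM (descending; ties broken by
#' transcript id ascending), entries below `min_pirpm` are dropped, and the
#' list is truncated to `n`.
#'
#' @param table a [transcript_association()] table.
#' @param n maximum number of targets.
#' @param min_pirpm minimum total piRPM.
#' @param rank_by "total", "sense" or "antisense" piRPM.
#' @return data.table of the selected rows, in rank order.
#' @export
select_top_targets <- function(table, n = 500, min_pirpm = 70,
                               rank_by = c("total", "sense", "antisense")) {
  rank_by <- match.arg(rank_by)
  col <- switch(rank_by, total = "total_pirpm", sense = "sense_pirpm",
                antisense = "antisense_pirpm")
  dt <- data.table::as.data.table(table)
  dt <- dt[dt[[col]] >= min_pirpm]
  dt <- dt[order(-dt[[col]], dt$transcript_id)]
  head(dt, n)
}

#' Intersect target lists from two replicates/breeds
#'
#' @param list1,list2 target tables or character vectors of transcript ids.
#' @return sorted character vector of shared transcript ids.
#' @export
reproducible_targets <- function(list1, list2) {
  ids <- function(x) if (is.character(x)) x else x$transcript_id
  sort(intersect(ids(list1), ids(list2)))
}

#' Union of per-stage reproducible target lists
#'
#' @param stage_lists named list (stage -> target table or id vector).
#' @return data.table with transcript_id and one logical membership column
#'   per stage.
#' @export
stage_union <- function(stage_lists) {
  if (length(stage_lists) == 0L) stopf("stage_union() needs >= 1 list")
  ids <- function(x) if (is.character(x)) x else x$transcript_id
  all_ids <- sort(unique(unlist(lapply(stage_lists, ids))))
  out <- data.table::data.table(transcript_id = all_ids)
  for (nm in names(stage_lists))
    out[, (nm) := all_ids %in% ids(stage_lists[[nm]])]
  out[]
}

#' Transcripts with differential piRNA association between two stages
#'
#' Keeps transcripts whose pseudocounted piRPM ratio between the two stages
#' exceeds `fold` (in either direction); the pseudocount makes zero values
#' comparable.
#'
#' @param table1,table2 [transcript_association()] tables for the two stages.
#' @param fold fold-change threshold (strict).
#' @param pseudo pseudocount in piRPM added to both values.
#' @param value "total", "sense" or "antisense" piRPM.
#' @return data.table: transcript_id, pirpm_1, pirpm_2, ratio, direction
#'   ("up_2" if stage 2 is higher).
#' @export
differential_association <- function(table1, table2, fold = 2, pseudo = 0.5,
                                     value = c("total", "sense", "antisense")) {
  value <- match.arg(value)
  col <- switch(value, total = "total_pirpm", sense = "sense_pirpm",
                antisense = "antisense_pirpm")
  t1 <- data.table::as.data.table(table1)[, c("transcript_id", col),
                                          with = FALSE]
  t2 <- data.table::as.data.table(table2)[, c("transcript_id", col),
                                          with = FALSE]
  data.table::setnames(t1, col, "pirpm_1")
  data.table::setnames(t2, col, "pirpm_2")
  m <- merge(t1, t2, by = "transcript_id", all = TRUE)
  m[is.na(pirpm_1), pirpm_1 := 0][is.na(pirpm_2), pirpm_2 := 0]
  m[, ratio := pmax(pirpm_1 + pseudo, pirpm_2 + pseudo) /
      pmin(pirpm_1 + pseudo, pirpm_2 + pseudo)]
  m[, direction := ifelse(pirpm_2 >= pirpm_1, "up_2", "up_1")]
  out <- m[ratio > fold]
  data.table::setorder(out, -ratio, transcript_id)
  out[]
}

#' Biotype breakdown of a target set
#'
#' @param targets character vector of transcript ids (or a table with a
#'   transcript_id column).
#' @param genes transcript table with biotype.
#' @return data.table with biotype, n; targets missing from the models are
#'   counted under "unannotated".
#' @export
biotype_breakdown <- function(targets, genes) {
  ids <- if (is.character(targets)) targets else targets$transcript_id
  genes <- data.table::as.data.table(genes)
  bt <- genes$biotype[match(ids, genes$transcript_id)]
  bt[is.na(bt)] <- "unannotated"
  known <- sort(unique(c(genes$biotype, "unannotated")))
  out <- data.table::data.table(biotype = known)
  cnt <- table(factor(bt, levels = known))
  out[, n := as.integer(cnt[biotype])]
  out[]
}
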