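#' Build a strand-aware feature index over TE and gene annotations
#'
#' Prepares interval stores for TE copies (with family), exons, and gene
#' spans; introns are gene span minus exons, so single-exon genes contribute
#' no intron space. TEs without a strand (".") are treated as "+"
#' (RepeatMasker convention).
#'
#' @param bundle a `pr_bundle`, or `NULL` if the tables are given directly.
#' @param te TE table (chrom, start, end, strand, family) if `bundle` is NULL.
#' @param genes,exons gene model tables if `bundle` is NULL.
#' @param chroms chromosome names of the mapping genome; annotation
#'   chromosomes absent from it raise an error naming the offender.
#' @return an object of class `pr_feature_index`.
#' @export
build_feature_index <- function(bundle = NULL, te = NULL, genes = NULL,
                                exons = NULL, chroms = NULL) {
  if (!is.null(bundle)) {
    te <- te %||% bundle$te
    genes <- genes %||% bundle$genes
    exons <- exons %||% bundle$exons
    chroms <- chroms %||% names(bundle$genome)
  }
  te <- data.table::as.data.table(te)
  genes <- data.table::as.data.table(genes)
  exons <- data.table::as.data.table(exons)
  if (!is.null(chroms)) {
    offender <- setdiff(unique(c(te$chrom, genes$chrom)), chroms)
    if (length(offender))
      stopf("annotation chromosome(s) not in genome: %s",
            paste(offender, collapse = ", "))
  }
  if (nrow(te)) {
    te[is.na(strand) | strand == "." | strand == "*", strand := "+"]
    if (!"family" %in% names(te)) te[, family := "unknown_family"]
    te[is.na(family) | family == "", family := "unknown_family"]
  }
  ex <- merge(exons, genes[, .(transcript_id, strand)], by = "transcript_id",
              sort = FALSE)
  structure(list(
    te = te,
    te_gr = if (nrow(te)) gr0(te$chrom, te$start, te$end) else GenomicRanges::GRanges(),
    exons = ex,
    exon_gr = if (nrow(ex)) gr0(ex$chrom, ex$start, ex$end) else GenomicRanges::GRanges(),
    genes = genes,
    gene_gr = if (nrow(genes)) gr0(genes$chrom, genes$start, genes$end)
              else GenomicRanges::GRanges(),
    chroms = chroms), class = "pr_feature_index")
}

#' Assign mapped reads to genomic categories
#'
#' Deterministic single category per read with precedence
#' TE > exon > intron > intergenic (>= 1 bp overlap); genic categories are
#' split into sense/antisense by read strand versus gene strand, sense taking
#' precedence when a read overlaps genes on both strands.
#'
#' @param reads MappedRead data.table.
#' @param index a `pr_feature_index`.
#' @return character vector of categories (`TE`, `exon_sense`,
#'   `exon_antisense`, `intron_sense`, `intron_antisense`, `intergenic`).
#' @export
assign_category <- function(reads, index) {
  n <- nrow(reads)
  if (n == 0L) return(character())
  if (!is.null(index$chroms)) {
    offender <- setdiff(unique(reads$chrom), index$chroms)
    if (length(offender))
      stopf("read chromosome(s) not in index: %s",
            paste(offender, collapse = ", "))
  }
  cat_out <- rep("intergenic", n)
  rgr <- gr0(reads$chrom, reads$start, reads$end)

  if (length(index$te_gr)) {
    te_hit <- IRanges::overlapsAny(rgr, index$te_gr)
    cat_out[te_hit] <- "TE"
  } else te_hit <- rep(FALSE, n)

  sense_flag <- function(gr_hits, feat_strand) {
    ## per read: TRUE if any sense hit, FALSE if only antisense, NA if none
    q <- S4Vectors::queryHits(gr_hits); s <- S4Vectors::subjectHits(gr_hits)
    same <- reads$strand[q] == feat_strand[s]
    out <- rep(NA, n)
    if (length(q)) {
      agg <- data.table::data.table(q = q, same = same)[, .(any_same = any(same)),
                                                        by = q]
      out[agg$q] <- agg$any_same
    }
    out
  }
  open <- !te_hit
  if (any(open) && length(index$exon_gr)) {
    h <- GenomicRanges::findOverlaps(rgr, index$exon_gr)
    ex_sense <- sense_flag(h, index$exons$strand)
    sel <- open & !is.na(ex_sense)
    cat_out[sel] <- ifelse(ex_sense[sel], "exon_sense", "exon_antisense")
    open <- open & is.na(ex_sense)
  }
  if (any(open) && length(index$gene_gr)) {
    h <- GenomicRanges::findOverlaps(rgr, index$gene_gr)
    g_sense <- sense_flag(h, index$genes$strand)
    sel <- open & !is.na(g_sense)
    cat_out[sel] <- ifelse(g_sense[sel], "intron_sense", "intron_antisense")
  }
  cat_out
}

#' Genomic association profile of a candidate set
#'
#' Copy-weighted fraction of the piRPM denominator in each genomic category;
#' fractions sum to 1.
#'
#' @param cands a `pr_candidates`.
#' @param index a `pr_feature_index`.
#' @return data.table with columns category, fraction (all six categories,
#'   zero-filled).
#' @export
association_profile <- function(cands, index) {
  if (cands$denom == 0) stopf("empty candidate set: profile undefined (denom = 0)")
  cats <- c("TE", "exon_sense", "exon_antisense", "intron_sense",
            "intron_antisense", "intergenic")
  a <- assign_category(cands$reads, index)
  dt <- data.table::data.table(category = a, copies = cands$reads$copies)
  agg <- dt[, .(fraction = sum(copies) / cands$denom), by = category]
  out <- data.table::data.table(category = cats)
  out <- merge(out, agg, by = "category", all.x = TRUE, sort = FALSE)
  out[is.na(fraction), fraction := 0]
  out[match(cats, category)][]
}

#' Per-TE-family sense/antisense piRPM profile
#'
#' Each TE-assigned read is attributed to the family of its maximal-overlap
#' TE copy (ties broken lexicographically by family name); orientation is
#' sense iff the read strand equals the annotated TE strand.
#'
#' @param cands a `pr_candidates`.
#' @param index a `pr_feature_index`.
#' @return data.table with columns family, sense_pirpm, antisense_pirpm.
#' @export
te_family_profile <- function(cands, index) {
  if (cands$denom == 0) stopf("empty candidate set: profile undefined (denom = 0)")
  reads <- cands$reads
  empty <- data.table::data.table(family = character(), sense_pirpm = numeric(),
                                  antisense_pirpm = numeric())
  if (nrow(reads) == 0L || !length(index$te_gr)) return(empty)
  keep <- assign_category(reads, index) == "TE"
  reads <- reads[keep]
  if (nrow(reads) == 0L) return(empty)
  rgr <- gr0(reads$chrom, reads$start, reads$end)
  h <- GenomicRanges::findOverlaps(rgr, index$te_gr)
  q <- S4Vectors::queryHits(h); s <- S4Vectors::subjectHits(h)
  ov <- IRanges::width(GenomicRanges::pintersect(rgr[q], index$te_gr[s]))
  dt <- data.table::data.table(q = q, family = index$te$family[s],
                               te_strand = index$te$strand[s], overlap_w = ov)
  data.table::setorder(dt, q, -overlap_w, family)
  best <- dt[, .SD[1L], by = q]
  best[, `:=`(copies = reads$copies[q],
              sense = reads$strand[q] == te_strand)]
  out <- best[, .(
    sense_pirpm = sum(copies[sense]) / cands$denom * 1e6,
    antisense_pirpm = sum(copies[!sense]) / cands$denom * 1e6), by = family]
  data.table::setorder(out, family)
  out[]
}
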