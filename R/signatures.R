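#' Genomic 5'-end position of mapped reads
#'
#' The 5' end is `start` for plus-strand reads and `end - 1` for minus-strand
#' reads (0-based coordinates).
#'
#' @param reads MappedRead data.table (columns start, end, strand).
#' @return integer vector of 5' positions.
#' @export
five_prime <- function(reads) {
  ifelse(reads$strand == "+", reads$start, reads$end - 1L)
}

#' Copy-weighted read-length spectrum in piRPM
#'
#' piRPM (piRNA reads per million) at each length is the copy count at that
#' length divided by the candidate-set denominator, times 10^6; the spectrum
#' over the candidate window sums to 10^6.
#'
#' @param cands a `pr_candidates`.
#' @return data.table with columns length, pirpm.
#' @export
length_spectrum <- function(cands) {
  if (cands$denom == 0) stopf("empty candidate set: piRPM undefined (denom = 0)")
  dt <- data.table::as.data.table(cands$reads)
  dt[, length_ := nchar(sequence)]
  out <- dt[, .(pirpm = sum(copies) / cands$denom * 1e6), by = .(length = length_)]
  data.table::setorder(out, length)
  out[]
}

#' Positional nucleotide composition and enrichment
#'
#' Copy-weighted base frequencies at positions 1..K from the 5' end, with
#' enrichment relative to a background: either the sample's overall base
#' frequency (copy-weighted over all read positions) or the uniform 0.25.
#' Reads shorter than a position are excluded from that position's
#' denominator. U is the display name for T.
#'
#' @param reads MappedRead data.table (or a `pr_candidates`).
#' @param K number of positions reported.
#' @param background `"sample"` or `"uniform"`.
#' @return list of class `pr_composition` with `freq` (4 x K matrix, rows
#'   U/A/C/G), `enrichment`, `background` (named numeric), `n_reads`.
#' @export
positional_composition <- function(reads, K = 15, background = c("sample",
                                                                 "uniform")) {
  background <- match.arg(background)
  if (inherits(reads, "pr_candidates")) reads <- reads$reads
  if (nrow(reads) == 0L) stopf("positional_composition() needs >= 1 read")
  bases <- c("T", "A", "C", "G")
  disp <- c("U", "A", "C", "G")
  freq <- matrix(NA_real_, 4L, K, dimnames = list(disp, seq_len(K)))
  len <- nchar(reads$sequence)
  for (k in seq_len(K)) {
    ok <- len >= k
    if (!any(ok)) next
    b <- substr(reads$sequence[ok], k, k)
    cnt <- vapply(bases, function(x) sum(reads$copies[ok][b == x]), numeric(1))
    freq[, k] <- cnt / sum(cnt)
  }
  bg <- if (background == "uniform") {
    setNames(rep(0.25, 4L), disp)
  } else {
    af <- Biostrings::alphabetFrequency(
      Biostrings::DNAStringSet(reads$sequence))[, c("T", "A", "C", "G"),
                                                drop = FALSE]
    tot <- colSums(af * reads$copies)
    setNames(tot / sum(tot), disp)
  }
  structure(list(freq = freq, enrichment = freq / bg, background = bg,
                 n_reads = sum(reads$copies)),
            class = "pr_composition")
}

## 5' keys of reads pairable at exactly overlap d: a + read at p pairs with a
## - read whose 5' is p + d - 1 (d-nt 5' overlap)
pairable_at <- function(reads, d, chrom_idx) {
  fp <- five_prime(reads)
  plus <- reads$strand == "+"
  kp <- pos_key(chrom_idx, fp)
  plus_keys <- unique(kp[plus]); minus_keys <- unique(kp[!plus])
  (plus & (pos_key(chrom_idx, fp + d - 1L) %in% minus_keys)) |
    (!plus & (pos_key(chrom_idx, fp - d + 1L) %in% plus_keys))
}

#' Ping-pong 5'-overlap spectrum
#'
#' For each overlap length d in 1..`d_max`, reports the copy-weighted piRPM
#' of reads having at least one opposite-strand partner whose 5' end overlaps
#' theirs by exactly d nt (partner 5' ends d - 1 nt apart). A read pairable
#' at several d contributes to each; each read counts once per d regardless
#' of how many partners it has there.
#'
#' @param cands a `pr_candidates`.
#' @param d_max maximum overlap length reported.
#' @return data.table with columns d, pirpm.
#' @export
overlap_spectrum <- function(cands, d_max = 20) {
  if (cands$denom == 0) stopf("empty candidate set: piRPM undefined (denom = 0)")
  reads <- cands$reads
  chrom_idx <- as.integer(factor(reads$chrom))
  out <- data.table::data.table(d = seq_len(d_max), pirpm = 0)
  for (d in seq_len(d_max)) {
    sel <- pairable_at(reads, d, chrom_idx)
    out[d, pirpm := sum(reads$copies[sel]) / cands$denom * 1e6]
  }
  out[]
}

#' Nucleotide composition of the ping-pong (d-overlap) subset
#'
#' Positional composition restricted to reads pairable at exactly `d` (both
#' partners); used for the 10A signature of secondary piRNAs. When no read is
#' pairable the function returns an explicit empty-subset object rather than
#' a zero matrix.
#'
#' @param cands a `pr_candidates`.
#' @param d overlap length defining the subset (default 10).
#' @param K positions reported.
#' @param background as in [positional_composition()].
#' @return a `pr_composition`; on an empty subset, a `pr_composition` with
#'   `n_reads = 0` and `NULL` matrices (test with [is_empty_subset()]).
#' @export
pingpong_subset_composition <- function(cands, d = 10, K = 15,
                                        background = "sample") {
  reads <- cands$reads
  if (nrow(reads) == 0L)
    return(structure(list(freq = NULL, enrichment = NULL, background = NULL,
                          n_reads = 0L), class = "pr_composition"))
  chrom_idx <- as.integer(factor(reads$chrom))
  sel <- pairable_at(reads, d, chrom_idx)
  if (!any(sel))
    return(structure(list(freq = NULL, enrichment = NULL, background = NULL,
                          n_reads = 0L), class = "pr_composition"))
  positional_composition(reads[sel], K = K, background = background)
}

#' Is a composition an empty-subset signal?
#' @param x a `pr_composition`.
#' @return logical.
#' @export
is_empty_subset <- function(x) {
  inherits(x, "pr_composition") && x$n_reads == 0L
}

#' Ping-pong enrichment z-score
#'
#' Standardises the overlap spectrum's value at d = 10 against the mean and
#' SD of the remaining overlap lengths. With a zero-SD background, z is 0 if
#' d = 10 equals the background mean and signed infinity otherwise.
#'
#' @param spectrum data.table from [overlap_spectrum()].
#' @param d focal overlap length (default 10).
#' @return numeric z-score.
#' @export
pingpong_enrichment <- function(spectrum, d = 10) {
  if (nrow(spectrum) < 5L) stopf("spectrum must cover >= 5 overlap lengths")
  v10 <- spectrum$pirpm[spectrum$d == d]
  rest <- spectrum$pirpm[spectrum$d != d]
  m <- mean(rest); s <- stats::sd(rest)
  if (s == 0) {
    if (v10 == m) return(0)
    return(sign(v10 - m) * Inf)
  }
  (v10 - m) / s
}
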