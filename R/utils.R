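#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' package functions are deterministic without clobbering the session RNG.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stopf("'seed' must be a single integer")
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive child seeds from a master seed
#'
#' @param seed master seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds, each comfortably below 2^31 so
#'   callers can add small offsets without overflow.
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(2147000000L, n))
}

## GRanges from 0-based half-open coordinates (package-internal convention)
#' @noRd
gr0 <- function(chrom, start, end, strand = "*") {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end),
                         strand = strand)
}

## write a data.table as a plain TSV with deterministic formatting
#' @noRd
write_tsv <- function(dt, path) {
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE, eol = "\n",
                     scipen = 50L)
  invisible(path)
}

#' @noRd
read_tsv <- function(path, ...) data.table::fread(path, sep = "\t", ...)

#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## fast exact-position key: chromosome index * 2^31 + position (double-exact)
#' @noRd
pos_key <- function(chrom_idx, pos) as.numeric(chrom_idx) * 2^31 + as.numeric(pos)

#' Reverse-complement a character vector of DNA sequences
#' @noRd
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## which query sequences occur as exact substrings (either orientation) of any
## subject sequence; queries must be >= 15 nt
#' @noRd
substring_hits <- function(query, subjects) {
  if (length(query) == 0L || length(subjects) == 0L)
    return(logical(length(query)))
  q <- Biostrings::DNAStringSet(query)
  if (min(Biostrings::width(q)) < 15L)
    stopf("substring_hits() requires queries of at least 15 nt")
  subj <- Biostrings::DNAStringSet(subjects)
  pd_f <- Biostrings::PDict(q, tb.start = 1L, tb.end = 15L)
  pd_r <- Biostrings::PDict(Biostrings::reverseComplement(q),
                            tb.start = 1L, tb.end = 15L)
  hit_f <- Biostrings::vcountPDict(pd_f, subj, collapse = 1L) > 0L
  hit_r <- Biostrings::vcountPDict(pd_r, subj, collapse = 1L) > 0L
  hit_f | hit_r
}
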