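#' Trim the 3' adaptor and collapse identical inserts
#'
#' For each read, the best adaptor alignment is located from a 10-nt seed
#' (matched with up to `max_mismatch` mismatches); the full aligned span
#' (seed start to read end, capped at the adaptor length) is then verified to
#' carry at most `max_mismatch` mismatches, and the read is cut at the seed
#' start. Reads with no verified adaptor, reads containing N, and inserts
#' outside `[min_len, max_len]` are discarded. Identical inserts are collapsed
#' with summed copy numbers.
#'
#' @param reads a [Biostrings::DNAStringSet] (or character vector) of raw
#'   reads.
#' @param adaptor 3' adaptor sequence (>= 10 nt).
#' @param min_len,max_len insert size window retained after trimming.
#' @param max_mismatch mismatches tolerated over the aligned adaptor span.
#' @return list with `reads` (data.table: read_id, sequence, copies, ordered
#'   by decreasing copies then sequence) and `tally` (input, with_n,
#'   no_adaptor, length_out, passed — all in read copies).
#' @export
trim_adaptor <- function(reads, adaptor = default_adaptor(), min_len = 15,
                         max_len = 45, max_mismatch = 1) {
  if (nchar(adaptor) < 10) stopf("adaptor must be at least 10 nt")
  reads <- Biostrings::DNAStringSet(reads)
  n_in <- length(reads)
  empty <- data.table::data.table(read_id = character(),
                                  sequence = character(), copies = integer())
  if (n_in == 0L)
    return(list(reads = empty,
                tally = list(input = 0L, with_n = 0L, no_adaptor = 0L,
                             length_out = 0L, passed = 0L)))

  has_n <- Biostrings::alphabetFrequency(reads)[, "N"] > 0L
  reads <- reads[!has_n]
  n_with_n <- sum(has_n)

  seed <- substr(adaptor, 1L, 10L)
  cut_at <- rep(NA_integer_, length(reads))
  if (length(reads)) {
    m <- Biostrings::vmatchPattern(seed, reads, max.mismatch = max_mismatch)
    si <- Biostrings::startIndex(m)
    si[vapply(si, is.null, logical(1))] <- list(integer())
    cand <- data.table::data.table(
      read = rep(seq_along(reads), lengths(si)),
      s = unlist(si, use.names = FALSE))
    if (nrow(cand)) {
      cand <- cand[s >= 1L]
      data.table::setorder(cand, read, s)
      cand[, rank_ := seq_len(.N), by = read]
      rlen <- Biostrings::width(reads)
      alen <- nchar(adaptor)
      r <- 1L
      repeat {
        cur <- cand[rank_ == r & is.na(cut_at[read])]
        if (nrow(cur) == 0L) break
        cur[, w := pmin(rlen[read] - s + 1L, alen)]
        for (wv in unique(cur$w)) {
          g <- cur[w == wv]
          spans <- Biostrings::subseq(reads[g$read], start = g$s, width = wv)
          ok <- Biostrings::vcountPattern(substr(adaptor, 1L, wv), spans,
                                          max.mismatch = max_mismatch) > 0L
          if (any(ok)) cut_at[g$read[ok]] <- g$s[ok]
        }
        r <- r + 1L
      }
    }
  }
  found <- !is.na(cut_at)
  n_no_adaptor <- sum(!found)
  ins_len <- cut_at[found] - 1L
  keep_len <- ins_len >= min_len & ins_len <= max_len
  n_length_out <- sum(!keep_len)

  idx <- which(found)[keep_len]
  inserts <- Biostrings::subseq(reads[idx], 1L, width = ins_len[keep_len])
  dt <- data.table::data.table(sequence = as.character(inserts))
  dt <- dt[, .(copies = .N), by = sequence]
  data.table::setorder(dt, -copies, sequence)
  dt[, read_id := sprintf("S%06d", seq_len(.N))]
  data.table::setcolorder(dt, c("read_id", "sequence", "copies"))
  list(reads = dt[],
       tally = list(input = n_in, with_n = n_with_n,
                    no_adaptor = n_no_adaptor, length_out = n_length_out,
                    passed = sum(dt$copies)))
}

#' Build an exact-match index over a genome
#'
#' Validates the genome alphabet and prepares it for all-occurrence exact
#' lookup of 15-45 nt queries on both strands. Query sets are matched with an
#' Aho-Corasick dictionary over their first 15 nt and verified to full
#' length, so lookups report every exact placement.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @return an object of class `pr_exact_index`.
#' @export
build_exact_index <- function(genome) {
  genome <- Biostrings::DNAStringSet(genome)
  if (length(genome) == 0L) stopf("genome is empty")
  if (is.null(names(genome))) stopf("genome chromosomes must be named")
  af <- Biostrings::alphabetFrequency(genome)
  extra <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0)) stopf("genome contains non-ACGTN characters")
  structure(list(genome = genome, chroms = names(genome)),
            class = "pr_exact_index")
}

#' All exact placements of a single query sequence
#'
#' @param index a `pr_exact_index`.
#' @param query a DNA sequence (15-45 nt).
#' @return data.table with chrom, start (0-based), end (half-open), strand.
#' @export
lookup_exact <- function(index, query) {
  q <- Biostrings::DNAString(query)
  rows <- list()
  for (ch in index$chroms) {
    for (st in c("+", "-")) {
      pat <- if (st == "+") q else Biostrings::reverseComplement(q)
      m <- Biostrings::matchPattern(pat, index$genome[[ch]])
      if (length(m))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          chrom = ch, start = IRanges::start(m) - 1L, end = IRanges::end(m),
          strand = st)
    }
  }
  out <- data.table::rbindlist(rows)
  if (nrow(out) == 0L)
    return(data.table::data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character()))
  data.table::setorder(out, chrom, start, strand)
  out
}

#' Map collapsed reads to the genome with no mismatches or indels
#'
#' Each sequence is looked up on both strands; a sequence with at least one
#' placement yields one primary `MappedRead` at the lexicographically
#' smallest (chrom, start, strand) hit, with `n_hits` recording the total
#' number of exact placements (the unique-mapper audit). Unmapped sequences
#' are tallied and dropped. Sequences containing N cannot match and are
#' counted as unmapped.
#'
#' @param reads data.table with read_id, sequence, copies (from
#'   [trim_adaptor()]).
#' @param index a `pr_exact_index`.
#' @return list with `reads` (data.table: read_id, chrom, start, end, strand,
#'   sequence, copies, n_hits) and `unmapped_copies`.
#' @export
map_exact <- function(reads, index) {
  if (nrow(reads) == 0L)
    return(list(reads = data.table::data.table(
      read_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), sequence = character(),
      copies = integer(), n_hits = integer()), unmapped_copies = 0L))
  clean <- !grepl("N", reads$sequence, fixed = TRUE)
  rr <- reads[clean]
  hits <- NULL
  if (nrow(rr)) {
    seqs <- Biostrings::DNAStringSet(rr$sequence)
    tb_w <- min(15L, min(Biostrings::width(seqs)))
    pd_f <- Biostrings::PDict(seqs, tb.start = 1L, tb.end = tb_w)
    pd_r <- Biostrings::PDict(Biostrings::reverseComplement(seqs),
                              tb.start = 1L, tb.end = tb_w)
    acc <- list()
    for (ch in index$chroms) {
      subj <- index$genome[[ch]]
      for (st in c("+", "-")) {
        m <- Biostrings::matchPDict(if (st == "+") pd_f else pd_r, subj)
        si <- Biostrings::startIndex(m)
        si[vapply(si, is.null, logical(1))] <- list(integer())
        nh <- lengths(si)
        if (sum(nh) == 0L) next
        acc[[length(acc) + 1L]] <- data.table::data.table(
          pat = rep(seq_along(nh), nh),
          start = unlist(si, use.names = FALSE) - 1L,
          chrom = ch, strand = st)
      }
    }
    hits <- data.table::rbindlist(acc)
  }
  if (is.null(hits) || nrow(hits) == 0L) {
    return(list(reads = data.table::data.table(
      read_id = character(), chrom = character(), start = integer(),
      end = integer(), strand = character(), sequence = character(),
      copies = integer(), n_hits = integer()),
      unmapped_copies = sum(reads$copies)))
  }
  nh <- hits[, .(n_hits = .N), by = pat]
  data.table::setorder(hits, pat, chrom, start, strand)
  prim <- hits[, .SD[1L], by = pat]
  prim <- merge(prim, nh, by = "pat", sort = TRUE)
  out <- data.table::data.table(
    read_id = rr$read_id[prim$pat], chrom = prim$chrom, start = prim$start,
    end = prim$start + nchar(rr$sequence[prim$pat]), strand = prim$strand,
    sequence = rr$sequence[prim$pat], copies = rr$copies[prim$pat],
    n_hits = prim$n_hits)
  data.table::setorder(out, chrom, start, strand, read_id)
  unmapped <- sum(reads$copies) - sum(out$copies)
  list(reads = out[], unmapped_copies = unmapped)
}

#' Remove reads whose sequences occur inside a blacklist sequence set
#'
#' A read is removed iff its sequence, or its reverse complement, occurs
#' exactly as a substring of any blacklist sequence (strand-insensitive
#' containment, matching no-mismatch mapping against rRNA/tRNA or miRNA
#' precursor sets).
#'
#' @param reads MappedRead data.table.
#' @param blacklist [Biostrings::DNAStringSet] (or character) of reference
#'   sequences; empty blacklist is a no-op.
#' @param label class label used in reporting.
#' @return list with `retained` (data.table), `removed_copies`, `label`.
#' @export
remove_by_sequence_class <- function(reads, blacklist, label = "blacklist") {
  if (length(blacklist) == 0L || nrow(reads) == 0L)
    return(list(retained = reads, removed_copies = 0L, label = label))
  hit <- substring_hits(reads$sequence, as.character(blacklist))
  list(retained = reads[!hit], removed_copies = sum(reads$copies[hit]),
       label = label)
}

#' Construct a candidate set
#'
#' @param sample_id,stage sample metadata.
#' @param reads MappedRead data.table restricted to the candidate window.
#' @return an object of class `pr_candidates` with `denom` = total copies
#'   (the piRPM denominator).
#' @export
new_candidate_set <- function(sample_id, stage, reads) {
  structure(list(sample_id = sample_id, stage = stage, reads = reads,
                 denom = sum(reads$copies)),
            class = "pr_candidates")
}

#' @export
print.pr_candidates <- function(x, ...) {
  cat(sprintf("pr_candidates '%s' (stage %s): %d sequences, %d copies\n",
              x$sample_id, x$stage, nrow(x$reads), x$denom))
  invisible(x)
}

#' Run the full piRNA candidacy cascade
#'
#' Applies, in fixed order: adaptor trimming + length window + collapsing;
#' exact genomic mapping (no mismatches, no indels); rRNA/tRNA removal;
#' known-miRNA removal; predicted-miRNA removal; 24-34 nt candidacy. A read
#' matching several blacklists is attributed to the earliest step. All
#' tallies are copy-weighted.
#'
#' @param raw a [Biostrings::DNAStringSet] of raw reads (with 3' adaptor) or
#'   a FASTQ/FASTA path.
#' @param genome named [Biostrings::DNAStringSet] or a `pr_exact_index`.
#' @param blacklists list with elements `rrna_trna`, `mirna`, `pred_mirna`
#'   (DNAStringSet or character; may be empty).
#' @param sample_id,stage sample metadata.
#' @param adaptor 3' adaptor sequence.
#' @param min_len,max_len,max_mismatch trimming parameters.
#' @param candidate_range length window (nt) defining piRNA candidacy.
#' @return list with `candidates` (a `pr_candidates`) and `report` (the
#'   FilterReport data.table: step, removed, remaining).
#' @export
run_candidacy <- function(raw, genome, blacklists, sample_id, stage,
                          adaptor = default_adaptor(), min_len = 15,
                          max_len = 45, max_mismatch = 1,
                          candidate_range = c(24L, 34L)) {
  if (is.character(raw) && length(raw) == 1L) raw <- read_reads(raw)
  index <- if (inherits(genome, "pr_exact_index")) genome
           else build_exact_index(genome)

  steps <- character(); removed <- integer(); remaining <- integer()
  log_step <- function(name, rem, left) {
    steps <<- c(steps, name); removed <<- c(removed, rem)
    remaining <<- c(remaining, left)
  }
  tr <- trim_adaptor(raw, adaptor, min_len, max_len, max_mismatch)
  log_step("input", 0L, tr$tally$input)
  log_step("adaptor_length",
           tr$tally$with_n + tr$tally$no_adaptor + tr$tally$length_out,
           tr$tally$passed)

  mp <- map_exact(tr$reads, index)
  log_step("genome_mapped", mp$unmapped_copies, sum(mp$reads$copies))

  cur <- mp$reads
  for (bl in list(list(key = "rrna_trna", step = "rrna_trna"),
                  list(key = "mirna", step = "known_mirna"),
                  list(key = "pred_mirna", step = "predicted_mirna"))) {
    res <- remove_by_sequence_class(cur, blacklists[[bl$key]] %||% character(),
                                    bl$step)
    cur <- res$retained
    log_step(bl$step, res$removed_copies, sum(cur$copies))
  }

  len <- nchar(cur$sequence)
  keep <- len >= candidate_range[1] & len <= candidate_range[2]
  log_step("candidate_24_34", sum(cur$copies[!keep]), sum(cur$copies[keep]))
  cands <- new_candidate_set(sample_id, stage, cur[keep])

  report <- data.table::data.table(step = steps, removed = removed,
                                   remaining = remaining)
  list(candidates = cands, report = report)
}
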