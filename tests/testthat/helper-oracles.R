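## Independent brute-force oracles and small fixture builders shared across
## the suite. The oracles deliberately avoid the package's own code paths
## (substring scans, exhaustive split searches, plain sort/filter).

## all exact placements of `query` on both strands, by naive substring scan
bf_all_hits <- function(genome, query) {
  if (!is.character(genome)) {
    nm <- names(genome)
    genome <- as.character(genome)
    names(genome) <- nm
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
  L <- nchar(query)
  rows <- list()
  for (ch in names(genome)) {
    gs <- genome[[ch]]
    n <- nchar(gs)
    if (n < L) next
    subs <- substring(gs, 1:(n - L + 1L), L:n)
    for (st in c("+", "-")) {
      pat <- if (st == "+") query else rc
      hit <- which(subs == pat)
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = ch, start = hit - 1L, end = hit - 1L + L, strand = st,
          stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  out[order(out$chrom, out$start, out$strand), , drop = FALSE]
}

## exhaustive split-point directionality classifier
bf_mode <- function(reads, mono_frac = 0.9, max_violation = 0.1) {
  total <- sum(reads$copies)
  plus <- sum(reads$copies[reads$strand == "+"])
  if (plus / total >= mono_frac) return("mono_plus")
  if ((total - plus) / total >= mono_frac) return("mono_minus")
  ord <- order(five_prime(reads), reads$start)
  st <- reads$strand[ord]; cp <- reads$copies[ord]
  best <- Inf
  for (k in 0:length(cp)) {
    first <- seq_len(k); rest <- setdiff(seq_along(cp), first)
    v1 <- sum(cp[first][st[first] == "+"]) + sum(cp[rest][st[rest] == "-"])
    v2 <- sum(cp[first][st[first] == "-"]) + sum(cp[rest][st[rest] == "+"])
    best <- min(best, v1, v2)
  }
  if (best / total <= max_violation) "bidirectional" else "dual_strand"
}

## plain-loop stage-enrichment classifier
bf_enrichment <- function(m, min_expr = 0.1, fold = 1.5) {
  stages <- colnames(m)
  out <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    v <- sort(m[i, ], decreasing = TRUE)
    if (v[1] < min_expr) out[i] <- "not_expressed"
    else if (v[1] >= fold * v[2])
      out[i] <- paste0(stages[which.max(m[i, ])], "-piRC")
    else out[i] <- "shared"
  }
  out
}

## plain sort-and-filter target selection
bf_top_targets <- function(tab, n = 500, min_pirpm = 70) {
  tab <- tab[tab$total_pirpm >= min_pirpm, ]
  tab <- tab[order(-tab$total_pirpm, tab$transcript_id), ]
  head(tab$transcript_id, n)
}

## random DNA of given length
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

## candidate set from an explicit read table; missing fields get defaults
make_cands <- function(df, sample_id = "S1", stage = "TEST") {
  dt <- data.table::as.data.table(df)
  n <- nrow(dt)
  if (!"read_id" %in% names(dt)) dt[, read_id := sprintf("S%06d", seq_len(n))]
  if (!"copies" %in% names(dt)) dt[, copies := 1L]
  if (!"n_hits" %in% names(dt)) dt[, n_hits := 1L]
  if (!"chrom" %in% names(dt)) dt[, chrom := "chr1"]
  if (!"sequence" %in% names(dt))
    dt[, sequence := vapply(end - start, function(L)
      paste(rep("T", L), collapse = ""), character(1))]
  new_candidate_set(sample_id, stage, dt)
}

## small reference bundle for generator-level tests
tiny_bundle <- function(seed = 11, genome_size = 3e5) {
  build_reference(genome_size = genome_size, n_chrom = 1,
                  te_families = c("CR1-B", "CR1-C"), te_copies_per_family = 5,
                  te_blocks = 2, te_block_copies = 2, n_genes = 4,
                  intragenic_te_genes = 1, n_rrna = 1, n_trna = 2,
                  n_mirna = 2, n_pred_mirna = 1, gene_margin = 3000,
                  te_block_margin = 3000, seed = seed)
}

## one well-isolated intergenic cluster spec on a tiny bundle
tiny_cluster_spec <- function(bundle, mode = "dual_strand", span = 20000,
                              ...) {
  free <- intergenic_space(bundle, min_len = span + 1000, margin = 500)
  data.table::setorder(free, chrom, start)
  if (nrow(free) == 0L) stop("no intergenic slot in tiny bundle")
  cluster_spec(free$chrom[1], free$start[1] + 500L,
               free$start[1] + 500L + span, mode = mode, ...)
}

## random transcript-association-like table
rand_assoc_table <- function(n, seed = NULL) {
  sense <- round(runif(n, 0, 150), 2)
  anti <- round(runif(n, 0, 150), 2)
  data.table::data.table(
    transcript_id = sprintf("TX%04d", sample.int(9999, n)),
    sense_pirpm = sense, antisense_pirpm = anti,
    total_pirpm = sense + anti,
    unique_fraction = runif(n), te_fraction = runif(n),
    biotype = sample(c("protein_coding", "uncharacterized", "snoRNA"), n,
                     replace = TRUE))
}
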