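#' Build a synthetic reference bundle
#'
#' Generates a small random genome with planted features: transposable-element
#' (TE) copies derived from per-family consensus sequences at a stated
#' divergence (partly organised into contiguous TE blocks, partly scattered,
#' with a few copies embedded in gene introns), gene models with exon blocks
#' and biotypes, rRNA/tRNA/miRNA loci whose sequences live on the genome, and
#' a transcript-by-dataset FPKM table. All coordinates are 0-based half-open.
#'
#' @param genome_size total genome size in bp (>= 100 kb).
#' @param n_chrom number of chromosomes; sizes decay geometrically.
#' @param te_families character vector of TE family names.
#' @param te_copies_per_family TE copies planted per family.
#' @param te_consensus_range length range (bp) for family consensus sequences.
#' @param te_divergence per-base substitution rate applied to each copy.
#' @param te_blocks number of contiguous TE blocks (piRNA-cluster-sized runs
#'   of back-to-back copies); remaining copies are scattered.
#' @param te_block_copies TE copies per block.
#' @param n_genes number of single-transcript gene models.
#' @param intragenic_te_genes number of genes that receive one intronic TE copy.
#' @param n_rrna,n_trna,n_mirna,n_pred_mirna counts of non-coding RNA loci.
#' @param n_rnaseq_datasets number of columns in the FPKM table.
#' @param base_freq background base composition of the random genome.
#' @param gene_margin,te_block_margin minimum distance (bp) of genes and TE
#'   blocks from other features. These are the loci that host piRNA clusters,
#'   so keeping them farther apart than a cluster detector's inter-read gap
#'   threshold keeps distinct planted clusters separable; the defaults give
#'   cluster densities comparable to real genomes (a handful per Mb).
#' @param seed integer seed; identical parameters and seed give byte-identical
#'   bundles.
#' @return an object of class `pr_bundle`: a list with elements `genome`
#'   (named [Biostrings::DNAStringSet]), `te`, `genes`, `exons`, `ncrna`,
#'   `fpkm` (data.tables), `te_consensus` (DNAStringSet) and `params`.
#' @export
build_reference <- function(genome_size = 1e6, n_chrom = 2,
                            te_families = paste0("CR1-", LETTERS[2:8]),
                            te_copies_per_family = 10,
                            te_consensus_range = c(600, 1500),
                            te_divergence = 0.2,
                            te_blocks = 5, te_block_copies = 4,
                            n_genes = 10, intragenic_te_genes = 4,
                            n_rrna = 2, n_trna = 4, n_mirna = 6,
                            n_pred_mirna = 4,
                            n_rnaseq_datasets = 3,
                            base_freq = c(A = 0.29, C = 0.21, G = 0.21, T = 0.29),
                            gene_margin = 12000, te_block_margin = 12000,
                            seed) {
  if (missing(seed)) stopf("build_reference() requires an explicit 'seed'")
  if (genome_size < 1e5) stopf("genome size must be at least 100 kb")
  n_te_total <- length(te_families) * te_copies_per_family
  if (te_blocks * te_block_copies > n_te_total)
    stopf("TE blocks require %d copies but only %d are available",
          te_blocks * te_block_copies, n_te_total)
  est <- n_genes * 6000 + n_te_total * mean(te_consensus_range) +
    n_rrna * 1500 + n_trna * 75 + (n_mirna + n_pred_mirna) * 85 +
    te_blocks * 500
  if (est > 0.55 * genome_size)
    stopf("requested features (~%d bp) exceed genome capacity (%d bp)",
          round(est), as.integer(genome_size))

  with_seed(seed, {
    ## --- chromosomes -----------------------------------------------------
    wts <- 0.62^(seq_len(n_chrom) - 1)
    chr_len <- floor(genome_size * wts / sum(wts))
    chr_names <- paste0("chr", seq_len(n_chrom))
    names(chr_len) <- chr_names
    bases <- names(base_freq)
    chr_chars <- lapply(chr_len, function(L)
      sample(bases, L, replace = TRUE, prob = base_freq))

    occupied <- lapply(chr_names, function(x) IRanges::IRanges())
    names(occupied) <- chr_names

    place <- function(len, margin = 300L) {
      for (i in seq_len(2000L)) {
        ch <- sample(chr_names, 1L, prob = chr_len)
        if (chr_len[[ch]] < len + 2L * margin + 10L) next
        s0 <- sample.int(chr_len[[ch]] - len - margin, 1L)  # 0-based start
        cand <- IRanges::IRanges(s0 + 1L - margin, s0 + len + margin)
        if (!IRanges::overlapsAny(cand, occupied[[ch]])) {
          occupied[[ch]] <<- c(occupied[[ch]],
                               IRanges::IRanges(s0 + 1L, s0 + len))
          return(list(chrom = ch, start = s0, end = s0 + len))
        }
      }
      stopf("could not place a feature of %d bp; genome too crowded", len)
    }

    plant <- function(ch, start0, seq_chr, strand) {
      if (strand == "-") seq_chr <- revcomp_chr(seq_chr)
      v <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
      chr_chars[[ch]][(start0 + 1L):(start0 + length(v))] <<- v
      invisible(NULL)
    }

    rand_seq <- function(len) paste(sample(bases, len, replace = TRUE,
                                           prob = base_freq), collapse = "")
    mutate_seq <- function(seq_chr, rate) {
      if (rate <= 0) return(seq_chr)
      v <- strsplit(seq_chr, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(v)) < rate)
      if (length(hit)) {
        v[hit] <- vapply(v[hit], function(b)
          sample(setdiff(bases, b), 1L), character(1L))
      }
      paste(v, collapse = "")
    }

    ## --- gene models ------------------------------------------------------
    genes <- vector("list", n_genes)
    exons <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      n_ex <- sample(3:5, 1L)
      ex_len <- sample(150:400, n_ex, replace = TRUE)
      in_len <- sample(1100:2500, max(n_ex - 1L, 0L), replace = TRUE)
      span <- sum(ex_len) + sum(in_len)
      loc <- place(span, margin = gene_margin)
      offs <- cumsum(c(0L, as.integer(rbind(ex_len, c(in_len, 0L)))[
        seq_len(2L * n_ex - 1L)]))
      ex_start <- loc$start + offs[seq(1L, by = 2L, length.out = n_ex)]
      tx_id <- sprintf("TX%04d", g)
      genes[[g]] <- data.table::data.table(
        transcript_id = tx_id, gene_id = sprintf("GENE%04d", g),
        chrom = loc$chrom, start = loc$start, end = loc$end,
        strand = sample(c("+", "-"), 1L),
        biotype = sample(c("protein_coding", "uncharacterized", "snoRNA"),
                         1L, prob = c(0.6, 0.3, 0.1)))
      exons[[g]] <- data.table::data.table(
        transcript_id = tx_id, exon_number = seq_len(n_ex),
        chrom = loc$chrom, start = as.integer(ex_start),
        end = as.integer(ex_start + ex_len))
    }
    genes <- data.table::rbindlist(genes)
    exons <- data.table::rbindlist(exons)

    ## --- ncRNA loci -------------------------------------------------------
    nc_spec <- data.table::data.table(
      class = rep(c("rRNA", "tRNA", "miRNA", "pred_miRNA"),
                  c(n_rrna, n_trna, n_mirna, n_pred_mirna)),
      len = rep(c(1500L, 75L, 85L, 85L),
                c(n_rrna, n_trna, n_mirna, n_pred_mirna)))
    ncrna <- vector("list", nrow(nc_spec))
    for (i in seq_len(nrow(nc_spec))) {
      loc <- place(nc_spec$len[i])
      ncrna[[i]] <- data.table::data.table(
        ncrna_id = sprintf("%s%02d", nc_spec$class[i], i),
        class = nc_spec$class[i], chrom = loc$chrom,
        start = loc$start, end = loc$end,
        strand = sample(c("+", "-"), 1L))
    }
    ncrna <- data.table::rbindlist(ncrna)

    ## --- TE consensus and copies -----------------------------------------
    cons_len <- sample(te_consensus_range[1]:te_consensus_range[2],
                       length(te_families), replace = TRUE)
    te_consensus <- vapply(cons_len, rand_seq, character(1L))
    names(te_consensus) <- te_families

    te <- list()
    te_n <- 0L
    add_te <- function(fam, ch, start0, len, strand, placement, block_id) {
      te_n <<- te_n + 1L
      cons <- te_consensus[[fam]]
      ## 5'-truncated copy (keep the consensus 3' end), then diverge
      frag <- substr(cons, nchar(cons) - len + 1L, nchar(cons))
      copy <- mutate_seq(frag, te_divergence)
      plant(ch, start0, copy, strand)
      te[[te_n]] <<- data.table::data.table(
        te_id = sprintf("TE%04d", te_n), family = fam, chrom = ch,
        start = start0, end = start0 + len, strand = strand,
        placement = placement, block_id = block_id)
    }

    fam_pool <- rep(te_families, te_copies_per_family)
    fam_pool <- sample(fam_pool)   # interleave families across placements
    k <- 0L
    for (b in seq_len(te_blocks)) {
      lens <- sample(600:1200, te_block_copies, replace = TRUE)
      lens <- pmin(lens, cons_len[match(fam_pool[k + seq_len(te_block_copies)],
                                        te_families)])
      gaps <- sample(0:20, te_block_copies, replace = TRUE)
      loc <- place(sum(lens) + sum(gaps), margin = te_block_margin)
      at <- loc$start
      for (j in seq_len(te_block_copies)) {
        k <- k + 1L
        add_te(fam_pool[k], loc$chrom, at, lens[j], sample(c("+", "-"), 1L),
               "block", sprintf("B%02d", b))
        at <- at + lens[j] + gaps[j]
      }
    }
    ## intronic copies
    eligible <- genes$transcript_id[genes$biotype != "snoRNA"]
    intron_tab <- exons[, if (.N > 1L)
      .(int_start = end[-.N], int_end = start[-1L]), by = transcript_id]
    intron_tab <- intron_tab[int_end - int_start >= 900L &
                               transcript_id %in% eligible]
    host <- head(unique(intron_tab$transcript_id), intragenic_te_genes)
    for (tx in host) {
      if (k >= length(fam_pool)) break
      row <- intron_tab[transcript_id == tx][1L]
      k <- k + 1L
      len <- min(row$int_end - row$int_start - 200L, 1200L,
                 cons_len[match(fam_pool[k], te_families)])
      add_te(fam_pool[k], genes[transcript_id == tx, chrom],
             row$int_start + 100L, len, sample(c("+", "-"), 1L),
             "intragenic", NA_character_)
    }
    ## scattered copies
    while (k < length(fam_pool)) {
      k <- k + 1L
      len <- min(sample(600:1400, 1L), cons_len[match(fam_pool[k], te_families)])
      loc <- place(len)
      add_te(fam_pool[k], loc$chrom, loc$start, len,
             sample(c("+", "-"), 1L), "scattered", NA_character_)
    }
    te <- data.table::rbindlist(te)
    data.table::setorder(te, chrom, start)

    ## --- genome assembly and ncRNA sequences ------------------------------
    genome <- Biostrings::DNAStringSet(vapply(chr_chars, paste,
                                              character(1L), collapse = ""))
    names(genome) <- chr_names
    nc_seq <- character(nrow(ncrna))
    for (i in seq_len(nrow(ncrna))) {
      s <- as.character(Biostrings::subseq(genome[[ncrna$chrom[i]]],
                                           ncrna$start[i] + 1L, ncrna$end[i]))
      nc_seq[i] <- if (ncrna$strand[i] == "-") revcomp_chr(s) else s
    }
    ncrna[, sequence := nc_seq]

    ## --- FPKM table: alternating expressed / silent transcripts -----------
    datasets <- sprintf("RNAseq%d", seq_len(n_rnaseq_datasets))
    fpkm <- data.table::CJ(transcript_id = genes$transcript_id,
                           dataset = datasets, sorted = TRUE)
    hi <- match(fpkm$transcript_id, genes$transcript_id) %% 2L == 1L
    fpkm[, fpkm := round(ifelse(hi, rlnorm(.N, log(8), 0.8),
                                runif(.N, 0, 0.9)), 3)]

    structure(list(
      genome = genome, te = te, genes = genes, exons = exons,
      ncrna = ncrna, fpkm = fpkm,
      te_consensus = Biostrings::DNAStringSet(te_consensus),
      params = list(genome_size = genome_size, n_chrom = n_chrom,
                    te_divergence = te_divergence, seed = seed)),
      class = "pr_bundle")
  })
}

#' @export
print.pr_bundle <- function(x, ...) {
  cat(sprintf(
    "pr_bundle: %d chromosome(s), %s bp; %d TE copies (%d families), %d genes, %d ncRNA loci\n",
    length(x$genome), format(sum(Biostrings::width(x$genome)), big.mark = ","),
    nrow(x$te), length(x$te_consensus), nrow(x$genes), nrow(x$ncrna)))
  invisible(x)
}

#' Intergenic space of a reference bundle
#'
#' Chromosome intervals (0-based half-open) not covered by any annotated
#' feature, padded by `margin`; used to site intergenic piRNA clusters.
#'
#' @param bundle a `pr_bundle`.
#' @param min_len minimum interval length to report.
#' @param margin padding around annotated features in bp.
#' @return data.table with columns chrom, start, end.
#' @export
intergenic_space <- function(bundle, min_len = 2000, margin = 300) {
  out <- lapply(names(bundle$genome), function(ch) {
    L <- length(bundle$genome[[ch]])
    occ <- IRanges::IRanges()
    for (tab in list(bundle$te, bundle$genes, bundle$ncrna)) {
      sub <- tab[tab$chrom == ch, ]
      if (nrow(sub))
        occ <- c(occ, IRanges::IRanges(pmax(sub$start + 1L - margin, 1L),
                                       pmin(sub$end + margin, L)))
    }
    free <- IRanges::setdiff(IRanges::IRanges(1L, L), IRanges::reduce(occ))
    free <- free[IRanges::width(free) >= min_len]
    data.table::data.table(chrom = ch, start = IRanges::start(free) - 1L,
                           end = IRanges::end(free))
  })
  data.table::rbindlist(out)
}
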