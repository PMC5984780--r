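test_that("reference bundles respect bounds and are deterministic", {
  b1 <- build_reference(genome_size = 2e5, n_chrom = 1,
                        te_families = c("famA", "famB"),
                        te_copies_per_family = 5, te_blocks = 2,
                        te_block_copies = 2, n_genes = 4,
                        intragenic_te_genes = 1, gene_margin = 3000,
                        te_block_margin = 3000, seed = 1)
  expect_equal(nrow(b1$te), 10L)
  expect_true(all(b1$te$start >= 0 & b1$te$end <= 2e5))
  expect_true(all(b1$genes$start >= 0 & b1$genes$end <= 2e5))
  expect_true(all(b1$exons$start >= b1$genes$start[
    match(b1$exons$transcript_id, b1$genes$transcript_id)]))

  b2 <- build_reference(genome_size = 2e5, n_chrom = 1,
                        te_families = c("famA", "famB"),
                        te_copies_per_family = 5, te_blocks = 2,
                        te_block_copies = 2, n_genes = 4,
                        intragenic_te_genes = 1, gene_margin = 3000,
                        te_block_margin = 3000, seed = 1)
  expect_identical(as.character(b1$genome), as.character(b2$genome))
  expect_identical(b1$te, b2$te)
  expect_identical(b1$genes, b2$genes)
  expect_identical(b1$fpkm, b2$fpkm)
})

test_that("zero-divergence TE copies are exact consensus substrings", {
  b <- build_reference(genome_size = 1.5e5, n_chrom = 1,
                       te_families = c("famA", "famB"),
                       te_copies_per_family = 4, te_divergence = 0,
                       te_blocks = 1, te_block_copies = 2, n_genes = 2,
                       intragenic_te_genes = 0, gene_margin = 2000,
                       te_block_margin = 2000, seed = 3)
  g <- as.character(b$genome[[1]])
  for (i in seq_len(nrow(b$te))) {
    slice <- substr(g, b$te$start[i] + 1L, b$te$end[i])
    if (b$te$strand[i] == "-")
      slice <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(slice)))
    cons <- as.character(b$te_consensus[[b$te$family[i]]])
    expect_true(grepl(slice, cons, fixed = TRUE),
                label = paste("copy", b$te$te_id[i], "in consensus"))
  }
})

test_that("reference builder rejects impossible sizing", {
  expect_error(build_reference(genome_size = 5e4, seed = 1), "100 kb")
  expect_error(build_reference(genome_size = 1.2e5, n_genes = 40, seed = 1),
               "capacity")
})

test_that("the FPKM table spans expressed and silent transcripts", {
  b <- tiny_bundle()
  mx <- b$fpkm[, max(fpkm), by = transcript_id]$V1
  expect_true(any(mx >= 1) && any(mx < 1))
})

test_that("forced ping-pong emission creates exact 10-nt 5' overlap pairs", {
  b <- tiny_bundle()
  sp <- tiny_cluster_spec(b, mode = "dual_strand",
                          stage_weights = c(X = 1), pingpong_frac = 1,
                          u1_prob = 0.9)
  sim <- simulate_sample(b, sp, "X", n_reads = 100,
                         noise = list(), adaptor = NULL, seed = 5)
  tr <- sim$truth
  expect_equal(nrow(tr), 100L)
  expect_setequal(unique(tr$role), c("pp_primary", "pp_partner"))
  prim <- tr[tr$role == "pp_primary", ]
  part <- tr[tr$role == "pp_partner", ]
  expect_equal(nrow(prim), 50L)
  ## every primary has a partner 9 nt downstream on the opposite strand
  fp_prim <- five_prime(prim)
  fp_part <- five_prime(part)
  off <- ifelse(prim$strand == "+", fp_prim + 9L, fp_prim - 9L)
  expect_true(all(off == fp_part))
  expect_true(all(prim$strand != part$strand))
  ## forced signature: primaries start with U, both members carry A at 10
  expect_true(all(substr(prim$sequence, 1, 1) == "T"))
  expect_true(all(substr(prim$sequence, 10, 10) == "A"))
  expect_true(all(substr(part$sequence, 10, 10) == "A"))
})

test_that("u1_prob = 1 forces a uracil start on every piRNA read", {
  b <- tiny_bundle()
  sp <- tiny_cluster_spec(b, mode = "mono_plus", stage_weights = c(X = 1),
                          u1_prob = 1, pingpong_frac = 0)
  sim <- simulate_sample(b, sp, "X", n_reads = 300, noise = list(),
                         adaptor = NULL, seed = 6)
  expect_true(all(substr(sim$truth$sequence, 1, 1) == "T"))
})

test_that("per-cluster read counts follow stage weights", {
  b <- tiny_bundle()
  free <- intergenic_space(b, min_len = 9000, margin = 500)
  data.table::setorder(free, chrom, start)
  sp1 <- cluster_spec(free$chrom[1], free$start[1] + 500,
                      free$start[1] + 4500, mode = "mono_plus",
                      stage_weights = c(E11G = 3, E14G = 1),
                      cluster_id = "c1")
  sp2 <- cluster_spec(free$chrom[1], free$start[1] + 4600,
                      free$start[1] + 8600, mode = "mono_plus",
                      stage_weights = c(E11G = 1, E14G = 3),
                      cluster_id = "c2")
  n <- 20000
  s11 <- simulate_sample(b, list(sp1, sp2), "E11G", n_reads = n,
                         noise = list(), adaptor = NULL, seed = 8)
  cnt <- table(s11$truth$source)
  p_hat <- cnt[["c1"]] / n
  se <- sqrt(0.75 * 0.25 / n)
  expect_lt(abs(p_hat - 0.75), 3 * se)
})

test_that("simulate_sample validates stage labels and cluster bounds", {
  b <- tiny_bundle()
  sp <- tiny_cluster_spec(b, mode = "mono_plus", stage_weights = c(X = 1))
  expect_error(simulate_sample(b, sp, "Y", n_reads = 10, noise = list(),
                               seed = 1), "unknown stage")
  bad <- cluster_spec("chrZ", 0, 2000, mode = "mono_plus",
                      stage_weights = c(X = 1))
  expect_error(simulate_sample(b, bad, "X", n_reads = 10, noise = list(),
                               seed = 1), "outside the genome")
})

test_that("degradation reads are class-separable from planted sequences", {
  b <- tiny_bundle()
  sp <- tiny_cluster_spec(b, mode = "mono_plus", stage_weights = c(X = 1))
  sim <- simulate_sample(b, sp, "X", n_reads = 2000,
                         noise = list(degradation = 300, rrna = 50, trna = 50,
                                      mirna = 30, pred_mirna = 20),
                         adaptor = NULL, seed = 9)
  tr <- sim$truth
  deg <- tr$sequence[tr$class == "degradation"]
  pir <- unique(tr$sequence[tr$class %in% c("piRNA_TE", "piRNA_cluster")])
  pir <- c(pir, as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(pir))))
  expect_false(any(deg %in% pir))
  ## and no degradation read hides inside an ncRNA locus sequence
  for (s in deg) expect_false(any(grepl(s, b$ncrna$sequence, fixed = TRUE)))
  ## adaptor handling: raw reads are insert + adaptor
  sim2 <- simulate_sample(b, sp, "X", n_reads = 50, noise = list(), seed = 2)
  expect_true(all(as.character(sim2$raw) ==
                    paste0(sim2$truth$sequence, default_adaptor())))
})

test_that("every read is an exact strand-adjusted genome substring", {
  b <- tiny_bundle()
  sp <- tiny_cluster_spec(b, mode = "dual_strand", stage_weights = c(X = 1),
                          pingpong_frac = 0.3)
  sim <- simulate_sample(b, sp, "X", n_reads = 500,
                         noise = list(degradation = 50), adaptor = NULL,
                         seed = 10)
  g <- as.character(b$genome[[1]])
  tr <- sim$truth
  slice <- substring(g, tr$start + 1L, tr$end)
  neg <- tr$strand == "-"
  slice[neg] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(slice[neg])))
  expect_identical(slice, tr$sequence)
})

test_that("bundles and samples survive a write/read round trip", {
  b <- tiny_bundle()
  sp <- tiny_cluster_spec(b, mode = "mono_plus", stage_weights = c(X = 1))
  sim <- simulate_sample(b, sp, "X", n_reads = 100, noise = list(), seed = 4)
  d <- withr::local_tempdir()
  write_bundle(b, d, samples = list(X = sim))
  b2 <- read_bundle(d)
  expect_identical(as.character(b2$genome), as.character(b$genome))
  expect_equal(b2$te, b$te, ignore_attr = TRUE)
  expect_equal(b2$genes[order(transcript_id)],
               b$genes[order(transcript_id)], ignore_attr = TRUE)
  expect_equal(b2$exons, b$exons[order(transcript_id, exon_number)],
               ignore_attr = TRUE)
  expect_equal(b2$fpkm, b$fpkm, ignore_attr = TRUE)
  reads <- read_reads(file.path(d, "reads_X.fastq"))
  expect_identical(as.character(reads), setNames(as.character(sim$raw),
                                                 names(sim$raw)))
  ## BED is 0-based half-open on disk
  bed_line <- strsplit(readLines(file.path(d, "te.bed"), n = 1L), "\t")[[1]]
  first_te <- b$te[order(chrom, start)][1]
  expect_identical(as.integer(bed_line[2]), first_te$start)
  expect_identical(as.integer(bed_line[3]), first_te$end)
})

test_that("GTF round trip converts 1-based exon coordinates consistently", {
  genes <- data.table::data.table(
    transcript_id = "TXh", gene_id = "Gh", chrom = "chr1",
    start = 100L, end = 1000L, strand = "+", biotype = "protein_coding")
  exons <- data.table::data.table(
    transcript_id = "TXh", exon_number = 1:3, chrom = "chr1",
    start = c(100L, 400L, 800L), end = c(200L, 500L, 1000L))
  p <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(genes, exons, p)
  lines <- readLines(p)
  ## on disk: 1-based inclusive
  ex1 <- strsplit(lines[2], "\t")[[1]]
  expect_identical(as.integer(ex1[4]), 101L)
  expect_identical(as.integer(ex1[5]), 200L)
  back <- read_gtf(p)
  expect_equal(back$exons[, .(transcript_id, exon_number, chrom, start, end)],
               exons, ignore_attr = TRUE)
  expect_equal(back$genes$start, 100L)
  expect_equal(back$genes$end, 1000L)
})

test_that("identical seeds give byte-identical emitted files", {
  b <- tiny_bundle()
  sp <- tiny_cluster_spec(b, mode = "mono_plus", stage_weights = c(X = 1))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    sim <- simulate_sample(b, sp, "X", n_reads = 500,
                           noise = list(degradation = 20), seed = 99)
    write_bundle(tiny_bundle(), d, samples = list(X = sim))
  }
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  h1 <- tools::md5sum(file.path(d1, f1)); h2 <- tools::md5sum(file.path(d2, f2))
  expect_identical(unname(h1), unname(h2))
})
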