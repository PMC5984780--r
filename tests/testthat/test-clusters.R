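## reads spread with a given 5' layout; sequences start with T so the U1
## gate passes unless stated otherwise
spread_reads <- function(fps, strand = "+", len = 28L, chrom = "chr1",
                         u1 = TRUE) {
  first <- if (u1) "T" else "G"
  strand <- rep(strand, length.out = length(fps))
  data.table::data.table(
    chrom = chrom,
    start = ifelse(strand == "+", fps, fps - len + 1L),
    end = ifelse(strand == "+", fps + len, fps + 1L),
    strand = strand,
    sequence = vapply(seq_along(fps), function(i)
      paste0(first, rand_dna(len - 1L)), character(1)),
    copies = 1L, n_hits = 1L,
    read_id = sprintf("r%04d", seq_along(fps)))
}

test_that("the detector forms gap-bounded loci and applies every threshold", {
  withr::local_seed(5)
  fps <- sort(sample(10000:12000, 50))
  cd <- make_cands(spread_reads(fps))
  cl <- detect_clusters(cd)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, min(fps))
  expect_equal(cl$end, max(fps) + 28L)
  expect_equal(cl$n_copies, 50L)
  expect_equal(cl$mode, "mono_plus")

  ## fewer distinct sequences than min_distinct: no cluster
  r <- spread_reads(sort(sample(10000:12000, 30)))
  r[, sequence := sequence[1]]
  expect_equal(nrow(detect_clusters(make_cands(r))), 0L)

  ## two groups separated by 20 kb become two clusters
  two <- make_cands(spread_reads(c(sort(sample(10000:12000, 30)),
                                   sort(sample(32000:34000, 30)))))
  expect_equal(nrow(detect_clusters(two)), 2L)

  ## low-density background is rejected
  sparse <- make_cands(spread_reads(seq(10000L, 110000L, by = 4000L)))
  expect_equal(nrow(detect_clusters(sparse)), 0L)

  ## U1 gate
  nou1 <- make_cands(spread_reads(sort(sample(10000:12000, 50)), u1 = FALSE))
  expect_equal(nrow(detect_clusters(nou1)), 0L)
  expect_equal(nrow(detect_clusters(make_cands(
    data.table::data.table(sequence = character(), copies = integer(),
                           chrom = character(), start = integer(),
                           end = integer(), strand = character())))), 0L)
})

test_that("directionality classification matches the exhaustive split oracle", {
  plus <- spread_reads(seq(1000L, 3000L, by = 50L), "+")
  expect_equal(classify_mode(plus), "mono_plus")
  minus <- spread_reads(seq(1000L, 3000L, by = 50L), "-")
  expect_equal(classify_mode(minus), "mono_minus")

  bi <- data.table::rbindlist(list(
    spread_reads(seq(1000L, 2000L, by = 50L), "-"),
    spread_reads(seq(2100L, 3100L, by = 50L), "+")))
  expect_equal(classify_mode(bi), "bidirectional")

  fps <- seq(1000L, 3000L, by = 50L)
  alt <- spread_reads(fps, rep(c("+", "-"), length.out = length(fps)))
  expect_equal(bf_mode(alt), "dual_strand")
  expect_equal(classify_mode(alt), "dual_strand")

  withr::local_seed(77)
  for (i in 1:40) {
    n <- sample(10:60, 1)
    r <- spread_reads(sort(sample(1000:8000, n)),
                      sample(c("+", "-"), n, replace = TRUE))
    r[, copies := sample(1:4, n, replace = TRUE)]
    expect_equal(classify_mode(r), bf_mode(r))
  }
})

test_that("cluster merging is transitive, idempotent and order-invariant", {
  mk <- function(start, end, id = "s") data.table::data.table(
    sample_id = id, chrom = "chr1", start = start, end = end,
    mode = "mono_plus", n_copies = 10L, n_distinct = 5L, u1_fraction = 1,
    density = 10)
  a <- mk(100L, 2000L, "A"); b <- mk(1500L, 3000L, "B")
  m <- merge_clusters(list(a, b))
  expect_equal(m$clusters[, .(start, end)],
               data.table::data.table(start = 100L, end = 3000L))
  d <- mk(10000L, 11000L, "C")
  m2 <- merge_clusters(list(a, d))
  expect_equal(nrow(m2$clusters), 2L)

  chain <- list(mk(0L, 10L), mk(5L, 20L), mk(15L, 30L))
  m3 <- merge_clusters(chain)
  expect_equal(m3$clusters[, .(start, end)],
               data.table::data.table(start = 0L, end = 30L))
  ## order invariance and idempotence
  m4 <- merge_clusters(rev(chain))
  expect_equal(m3$clusters, m4$clusters)
  m5 <- merge_clusters(list(m3$clusters[, .(sample_id = cluster_id, chrom,
                                            start, end)]))
  expect_equal(m5$clusters[, .(chrom, start, end)],
               m3$clusters[, .(chrom, start, end)])
  ## disjoint per chromosome
  expect_true(all(diff(m3$clusters$start) > 0 | nrow(m3$clusters) == 1L))
})

test_that("transcript extension reaches the fixpoint and respects the FPKM gate", {
  mk_reg <- function() merge_clusters(list(data.table::data.table(
    sample_id = "s", chrom = "chr1", start = 1000L, end = 2000L,
    mode = "mono_plus", n_copies = 10L, n_distinct = 5L,
    u1_fraction = 1, density = 10)))
  genes <- data.table::data.table(
    transcript_id = c("TXa", "TXb", "TXc"), gene_id = c("Ga", "Gb", "Gc"),
    chrom = "chr1", start = c(1800L, 3900L, 1850L),
    end = c(4000L, 6000L, 5000L), strand = "+", biotype = "protein_coding")
  fpkm_hi <- data.table::data.table(
    transcript_id = c("TXa", "TXb", "TXc"), dataset = "d1",
    fpkm = c(2.3, 1.7, 0.5))
  ## single expressed transcript extends the cluster over its span
  ext1 <- extend_by_transcripts(mk_reg(), genes[1], fpkm_hi[1])
  expect_equal(ext1$clusters[, .(start, end)],
               data.table::data.table(start = 1000L, end = 4000L))
  ## FPKM below the gate leaves boundaries unchanged
  ext0 <- extend_by_transcripts(mk_reg(), genes[3], fpkm_hi[3])
  expect_equal(ext0$clusters[, .(start, end)],
               data.table::data.table(start = 1000L, end = 2000L))
  ## chained transcripts require iteration to the fixpoint
  ext2 <- extend_by_transcripts(mk_reg(), genes[1:2], fpkm_hi[1:2])
  expect_equal(ext2$clusters[, .(start, end)],
               data.table::data.table(start = 1000L, end = 6000L))
  ## a single overlap pass stops at TXa's span: fixpoint differs
  single_pass_end <- 4000L
  expect_gt(ext2$clusters$end, single_pass_end)
  ## boundaries only grow
  expect_lte(ext2$clusters$start, 1000L)
})

test_that("piRPKM quantification normalises and assigns by 5' ownership", {
  reg <- merge_clusters(list(data.table::data.table(
    sample_id = "s", chrom = "chr1", start = 1000L, end = 6000L,
    mode = "mono_plus", n_copies = 50L, n_distinct = 10L,
    u1_fraction = 1, density = 10)))
  inside <- spread_reads(seq(1200L, 5800L, length.out = 50L))
  cd <- new_candidate_set("s1", "BC", inside)
  cd$denom <- 1e6   # treat as a million-read library
  q <- quantify_pirpkm(reg, list(s1 = cd))
  expect_equal(unname(q$sample_matrix[1, 1]), 50 / 5)

  ## normalisation invariance under copy scaling
  cd2 <- new_candidate_set("s1", "BC", data.table::copy(inside)[
    , copies := copies * 10L])
  cd2$denom <- 1e7
  q2 <- quantify_pirpkm(reg, list(s1 = cd2))
  expect_equal(q$sample_matrix, q2$sample_matrix, tolerance = 1e-12)

  ## a 5' exactly on the end coordinate is outside (half-open)
  edge <- spread_reads(c(5999L, 6000L))
  cde <- new_candidate_set("s1", "BC", edge)
  qe <- quantify_pirpkm(reg, list(s1 = cde))
  expect_equal(unname(qe$sample_matrix[1, 1]),
               1 / 5 / (cde$denom / 1e6))

  ## stage aggregation averages member samples
  cd3 <- new_candidate_set("sA", "E11G", inside)
  cd4 <- new_candidate_set("sB", "E14G", inside[1:25])
  q3 <- quantify_pirpkm(reg, list(sA = cd3, sB = cd4))
  expect_equal(unname(q3$stage_matrix[1, "EG"]),
               mean(q3$sample_matrix[1, ]))
  expect_error(quantify_pirpkm(reg, list(z = new_candidate_set("z", "BC",
    inside[0]))), "denom = 0")
})

test_that("stage-enrichment labels match examples and the brute-force oracle", {
  m <- rbind(c(0.5, 0.2, 0.1, 0.05),
             c(0.5, 0.4, 0.1, 0.05),
             c(0.05, 0.04, 0, 0))
  colnames(m) <- c("BC", "PGC", "EG", "AT")
  lab <- classify_stage_enrichment(m)
  expect_equal(lab$label, c("BC-piRC", "shared", "not_expressed"))

  withr::local_seed(13)
  rm <- matrix(round(runif(4000, 0, 0.6), 3), ncol = 4,
               dimnames = list(NULL, c("BC", "PGC", "EG", "AT")))
  expect_equal(classify_stage_enrichment(rm)$label, bf_enrichment(rm))
  ## exact tie between the top two stages cannot satisfy the fold rule
  tie <- matrix(c(0.4, 0.4, 0.1, 0), 1, dimnames = list(NULL, colnames(m)))
  expect_equal(classify_stage_enrichment(tie)$label, "shared")
})

test_that("classical MDS reproduces exact low-dimensional configurations", {
  ## identical samples embed at distance zero
  m <- matrix(c(1, 2, 3, 1, 2, 3, 5, 1, 0.2), nrow = 3,
              dimnames = list(paste0("c", 1:3), paste0("s", 1:3)))
  fit <- mds_embedding(m)
  expect_lt(sqrt(sum((fit$points[1, ] - fit$points[2, ])^2)), 1e-6)

  ## collinear configuration: first eigenvalue carries all variation
  line <- matrix(10^c(0, 1, 2) - 0.01, nrow = 1,
                 dimnames = list("c1", paste0("s", 1:3)))
  fit2 <- mds_embedding(line)
  expect_equal(fit2$eig_fraction[1], 1)

  ## a 3-point planar configuration is reproduced exactly
  withr::local_seed(3)
  m3 <- matrix(runif(12, 0.1, 50), nrow = 4,
               dimnames = list(paste0("c", 1:4), paste0("s", 1:3)))
  fit3 <- mds_embedding(m3)
  want <- dist(t(log10(m3 + 0.01)))
  got <- dist(fit3$points)
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-8)
  expect_error(mds_embedding(m3[, 1:2]), ">= 3")
})

test_that("synteny anchors flag strictly contained partner clusters", {
  anchor <- list(name = "A1", species = list(
    gg = list(chrom = "chr1", geneA = c(1000, 4000), geneB = c(9000, 12000)),
    mm = list(chrom = "5", geneA = c(100, 500), geneB = c(3000, 3600))))
  cl_in <- list(gg = data.table::data.table(chrom = "chr1", start = 5000L,
                                            end = 8000L),
                mm = data.table::data.table(chrom = "5", start = 800L,
                                            end = 1500L))
  res <- synteny_check(list(anchor), cl_in)
  expect_true(res$conserved)

  cl_missing <- cl_in; cl_missing$mm <- cl_missing$mm[0]
  expect_false(synteny_check(list(anchor), cl_missing)$conserved)

  ## straddling geneB start is not "between"
  cl_straddle <- cl_in
  cl_straddle$gg <- data.table::data.table(chrom = "chr1", start = 8000L,
                                           end = 9500L)
  expect_false(synteny_check(list(anchor), cl_straddle)$conserved)

  bad <- list(name = "A2", species = list(
    gg = list(chrom = "chr1", geneA = c(1000, 9500), geneB = c(9000, 12000))))
  expect_error(synteny_check(list(bad), cl_in), "overlap")
})
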