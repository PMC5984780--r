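## Deterministic writers for the standard text formats, plus readers that go
## through established parsers (Biostrings for FASTA/FASTQ, rtracklayer for
## BED/GTF). Writers are in-package so that repeated runs with the same seed
## give byte-identical files. All in-memory coordinates are 0-based half-open;
## BED is written as-is, GTF converts to 1-based inclusive.

#' Write a reference bundle (and optionally simulated samples) to disk
#'
#' Emits `genome.fa`, `te.bed` (BED6, name = family), `genes.gtf`
#' (transcript + exon lines, 1-based inclusive), `ncrna.bed` plus per-class
#' blacklist FASTAs (`rrna_trna.fa`, `mirna.fa`, `pred_mirna.fa`),
#' `fpkm.tsv`, and for each sample a FASTQ and a truth-manifest TSV.
#'
#' @param bundle a `pr_bundle`.
#' @param out_dir output directory (created if needed).
#' @param samples optional named list of `pr_sim_sample` objects.
#' @return invisibly, the vector of written paths.
#' @export
write_bundle <- function(bundle, out_dir, samples = NULL) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", out_dir)
  paths <- character()
  add <- function(p) { paths <<- c(paths, p); p }

  Biostrings::writeXStringSet(bundle$genome, add(file.path(out_dir, "genome.fa")),
                              width = 70L)

  write_bed6(bundle$te[, .(chrom, start, end, name = family, score = 0L,
                           strand)],
             add(file.path(out_dir, "te.bed")))
  write_gtf(bundle$genes, bundle$exons, add(file.path(out_dir, "genes.gtf")))
  write_bed6(bundle$ncrna[, .(chrom, start, end, name = ncrna_id, score = 0L,
                              strand)],
             add(file.path(out_dir, "ncrna.bed")))

  ncs <- Biostrings::DNAStringSet(bundle$ncrna$sequence)
  names(ncs) <- bundle$ncrna$ncrna_id
  Biostrings::writeXStringSet(
    ncs[bundle$ncrna$class %in% c("rRNA", "tRNA")],
    add(file.path(out_dir, "rrna_trna.fa")), width = 70L)
  Biostrings::writeXStringSet(ncs[bundle$ncrna$class == "miRNA"],
                              add(file.path(out_dir, "mirna.fa")), width = 70L)
  Biostrings::writeXStringSet(ncs[bundle$ncrna$class == "pred_miRNA"],
                              add(file.path(out_dir, "pred_mirna.fa")),
                              width = 70L)
  write_tsv(bundle$fpkm, add(file.path(out_dir, "fpkm.tsv")))
  write_tsv(bundle$ncrna, add(file.path(out_dir, "ncrna_loci.tsv")))
  write_tsv(bundle$te, add(file.path(out_dir, "te_full.tsv")))

  for (nm in names(samples)) {
    s <- samples[[nm]]
    write_fastq(s$raw, add(file.path(out_dir, sprintf("reads_%s.fastq", nm))))
    write_tsv(s$truth, add(file.path(out_dir, sprintf("truth_%s.tsv", nm))))
  }
  invisible(paths)
}

#' Read back a bundle written by [write_bundle()]
#'
#' Genome and blacklists are parsed with Biostrings, BED with rtracklayer
#' (converted to the package's 0-based half-open convention), GTF with
#' rtracklayer (1-based inclusive, converted).
#'
#' @param dir directory written by [write_bundle()].
#' @return a `pr_bundle` (without TE consensus sequences, which are not
#'   serialised).
#' @export
read_bundle <- function(dir) {
  genome <- Biostrings::readDNAStringSet(file.path(dir, "genome.fa"))
  te_full <- read_tsv(file.path(dir, "te_full.tsv"), na.strings = "")
  gtf <- read_gtf(file.path(dir, "genes.gtf"))
  ncrna <- read_tsv(file.path(dir, "ncrna_loci.tsv"))
  fpkm <- read_tsv(file.path(dir, "fpkm.tsv"))
  structure(list(genome = genome, te = te_full, genes = gtf$genes,
                 exons = gtf$exons, ncrna = ncrna, fpkm = fpkm,
                 te_consensus = NULL, params = NULL),
            class = "pr_bundle")
}

## --- low-level writers/readers --------------------------------------------

#' Write a BED6 file (0-based half-open, as per the BED convention)
#' @param dt data.table with columns chrom, start, end, name, score, strand.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_bed6 <- function(dt, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", dt$chrom, as.integer(dt$start),
                   as.integer(dt$end), dt$name, format(dt$score, trim = TRUE),
                   dt$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED6 file into the internal 0-based convention
#' @param path BED file path.
#' @return data.table with chrom, start, end, name, score, strand.
#' @export
read_bed6 <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = IRanges::start(gr) - 1L, end = IRanges::end(gr),
    name = gr$name %||% NA_character_,
    score = as.numeric(gr$score %||% NA_real_),
    strand = as.character(GenomicRanges::strand(gr)))
}

#' Write gene models as GTF (1-based inclusive coordinates)
#' @param genes transcript table (0-based half-open internally).
#' @param exons exon table.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_gtf <- function(genes, exons, path) {
  attr_tx <- function(g, extra = "")
    sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";%s',
            g$gene_id, g$transcript_id, g$biotype, extra)
  tx_lines <- sprintf("%s\tstagepir\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                      genes$chrom, genes$start + 1L, genes$end,
                      genes$strand, attr_tx(genes))
  ex <- merge(exons, genes[, .(transcript_id, gene_id, strand, biotype)],
              by = "transcript_id", sort = FALSE)
  data.table::setorder(ex, transcript_id, exon_number)
  ex_lines <- sprintf(
    "%s\tstagepir\texon\t%d\t%d\t.\t%s\t.\t%s",
    ex$chrom, ex$start + 1L, ex$end, ex$strand,
    attr_tx(ex, sprintf(' exon_number "%d";', ex$exon_number)))
  ## interleave: each transcript followed by its exons, transcripts in
  ## table order
  ord <- order(match(c(genes$transcript_id, ex$transcript_id),
                     genes$transcript_id),
               c(rep(0L, nrow(genes)), ex$exon_number))
  writeLines(c(tx_lines, ex_lines)[ord], path)
  invisible(path)
}

#' Read a GTF of gene models into the internal 0-based convention
#' @param path GTF path.
#' @return list with `genes` and `exons` data.tables.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = IRanges::start(gr) - 1L, end = IRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type), gene_id = md$gene_id,
    transcript_id = md$transcript_id,
    biotype = md$gene_biotype,
    exon_number = suppressWarnings(as.integer(md$exon_number)))
  genes <- dt[type == "transcript",
              .(transcript_id, gene_id, chrom, start, end, strand, biotype)]
  exons <- dt[type == "exon",
              .(transcript_id, exon_number, chrom, start, end)]
  data.table::setorder(exons, transcript_id, exon_number)
  list(genes = genes, exons = exons)
}

#' Write reads as FASTQ with constant qualities
#' @param reads a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(reads)))
  Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read small-RNA reads from FASTQ or FASTA
#' @param path input path; format inferred from the extension
#'   (`.fastq`/`.fq` vs anything else).
#' @return a named [Biostrings::DNAStringSet].
#' @export
read_reads <- function(path) {
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path)) "fastq" else "fasta"
  Biostrings::readDNAStringSet(path, format = fmt)
}
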