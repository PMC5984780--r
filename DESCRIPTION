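Package: stagepir
Title: Stage-Resolved piRNA Candidate, Signature and Cluster Analysis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for stage-resolved analysis of
    PIWI-interacting RNAs (piRNAs) from 3'-end-2'-O-methylation-enriched small
    RNA sequencing. Implements high-confidence piRNA candidate identification
    (adaptor trimming, read collapsing, exact-match genomic mapping with no
    mismatches, hierarchical rRNA/tRNA/miRNA contaminant removal, 24-34 nt
    candidacy), piRNA signature statistics (length spectra in piRPM, positional
    1U/10A nucleotide composition, ping-pong 5'-overlap spectra), genomic and
    transposable-element association profiling, deterministic piRNA cluster
    detection including dual-strand clusters, cross-sample cluster merging with
    transcript-based boundary extension, piRPKM quantification,
    stage-enrichment classification, multidimensional scaling, synteny checks,
    and piRNA-associated transcript selection. Ships a synthetic-data generator
    that emits a reference bundle and stage-dependent read sets with a full
    ground-truth manifest, so every pipeline stage is exercised against planted
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
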