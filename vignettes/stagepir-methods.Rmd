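---
title: "Stage-resolved piRNA analysis: models, parameters and design"
author: "stagepir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved piRNA analysis: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

stagepir analyses 3'-end-2'-O-methylation-enriched small RNA sequencing
across germ-cell developmental stages. Periodate oxidation destroys the
ligatable 3' end of most small RNAs but spares piRNAs, whose 3' ends are
2'-O-methylated, so an oxidised library is strongly enriched for piRNAs;
the pipeline treats its input as already enriched and does the computational
half of the job: candidate identification, signature statistics, genomic and
transposable-element (TE) association, cluster detection and cross-stage
cluster expression analysis, and selection of piRNA-associated transcripts.
A synthetic-data generator with a complete truth manifest makes every stage
testable against planted ground truth.

# The candidacy cascade

Candidates are defined operationally by a fixed filter order:

1. **3' adaptor trimming.** The adaptor's first 10 nt act as a seed, matched
   with at most one mismatch; the full aligned span (seed start to read end,
   capped at the adaptor length) is then verified to carry at most one
   mismatch, and the read is cut at the seed start. Among candidate
   positions the earliest verified one wins. Reads without a verified
   adaptor, reads containing N (which can never map under an exact-match
   contract), and inserts outside 15-45 nt are discarded. Identical inserts
   are collapsed with summed copy counts; all downstream tallies are
   copy-weighted, matching reads-per-million semantics.
2. **Exact genomic mapping.** No mismatches, no indels, both strands. Every
   placement of a sequence is found (an Aho-Corasick dictionary over the
   first 15 nt plus full-length verification); a mapped sequence receives
   one *primary* placement — the lexicographically smallest
   (chromosome, start, strand) hit — while `n_hits` records the total
   placement count for the unique-mapper audit. The lexicographic rule
   replaces the nondeterministic "report one alignment" behaviour of
   short-read aligners with a reproducible choice.
3. **Hierarchical contaminant removal.** rRNA/tRNA first, then known miRNA
   precursors, then predicted precursors. A read is removed iff its sequence
   (or reverse complement) occurs exactly as a substring of a blacklist
   sequence. Sequence-level containment captures junction-spanning
   contaminants without a spliced aligner; a read matching several
   blacklists is attributed to the earliest step, which the suite asserts
   with a constructed collision.
4. **24-34 nt candidacy.** The surviving copy total is the piRPM
   denominator (piRNA reads per million candidate reads).

The per-step report (`FilterReport`) is conservative by construction:
removed + remaining at each step equals the previous remaining.

# Signature statistics

* **Length spectrum**: copy-weighted piRPM per read length; sums to 10^6
  over the candidate window.
* **Positional composition**: copy-weighted base frequencies at positions
  1..15 from the 5' end (U displayed for T); reads shorter than a position
  drop out of that position's denominator. Enrichment is frequency over
  background; the default background is the sample's own overall base
  composition rather than 0.25, because synthetic and real genomes are not
  uniform — both options are exposed.
* **Overlap spectrum**: for each d in 1..20, the piRPM of reads with at
  least one opposite-strand partner whose 5' end is exactly d − 1 nt away
  (a d-nt 5' overlap). Each read counts once per d however many partners it
  has, i.e. the statistic counts pairable reads, not pairs. Pairing uses
  each sequence's primary placement, consistent with the mapping policy.
* **Ping-pong subset composition**: positional composition restricted to
  reads pairable at exactly d = 10, where secondary piRNAs show the 10A
  signature. An empty subset returns an explicit empty-subset object, not a
  zero matrix, so "no ping-pong" is distinguishable from "ping-pong with
  zero A".
* **Ping-pong z-score**: the d = 10 value standardised against the mean and
  SD of the other overlap lengths. A zero-SD background yields 0 when
  d = 10 equals the background and signed infinity otherwise.

# Annotation

Categories follow the precedence TE > exon > intron > intergenic with
>= 1 bp overlap; genic categories split into sense/antisense by read versus
gene strand (sense wins when both orientations are hit). Introns are gene
span minus exons, so single-exon genes contribute no intron space. TE
orientation uses the annotated repeat strand, with strandless records
treated as "+" (the RepeatMasker convention); a read overlapping several
TE copies is attributed to the maximal-overlap copy, ties broken
lexicographically by family for determinism.

# Cluster analysis

## Detection

The detector is deliberately deterministic: reads sorted by 5' position form
runs wherever consecutive 5' gaps are at most `max_gap` (default 5000 nt);
a run becomes a cluster iff it has >= 5 distinct sequences, >= 10 copies,
>= 10 copies/kb, >= 50% 1U reads and a span of >= 1 kb. All thresholds are
exposed. A probabilistic read-density model would be harder to test and its
published adaptation is under-specified; the gap detector gives exact
contracts at the price of one documented weakness: any background denser
than one read per `max_gap` chains runs together. Consequently the
synthetic fixture keeps uniform degradation below that rate, and under a
multi-sample union the merged boundaries still creep outward by up to a few
kilobases around true clusters — visible as inflated merged spans, not as
false cluster calls, since pure-background runs fail the density and copy
thresholds. Boundary-sensitive claims are therefore evaluated on noiseless
fixtures and expression claims on the noisy default.

## Directionality

A cluster is mono-directional when >= 90% of copies share a strand.
Otherwise the best single split of the 5'-ordered reads into two contiguous
opposite-strand blocks is computed (both orientations, prefix sums);
<= 10% of copies violating the best split means bidirectional, more means
dual-strand. The suite checks this against an exhaustive split-point oracle.

## Merging, extension, quantification

Same-chromosome clusters overlapping by >= 1 bp are unioned transitively
(strand-agnostic, since dual-strand clusters make stranded merging
ill-defined); the operation is idempotent and order-invariant. Merged
clusters then grow, to a fixpoint, over any overlapping transcript with
FPKM >= 1 in at least one RNA-seq dataset — a piRNA precursor and a
sense-overlapping mRNA precursor are not distinguishable by Pol II
transcription evidence, so the expressed transcript's span is annexed.
Growth is monotone and bounded; a chained-transcript fixture in the suite
shows a single pass is not the fixpoint. Clusters that grow into one
another are re-merged. The copies assignable to clusters before and after
extension are recorded per sample.

Expression is piRPKM: cluster copies / (cluster kb x candidate millions).
A read belongs to a cluster iff its 5' position lies inside it (half-open),
giving boundary-straddling reads a unique owner. Scaling every copy count
in a sample by a constant leaves piRPKM unchanged. Stage values average the
member samples of a stage group (E11G and E14G form EG); an arithmetic mean
is the simplest defensible aggregator for a group treated as one class.

## Stage enrichment, MDS, synteny

A cluster is stage-enriched when its top stage is >= 0.1 piRPKM and
>= 1.5-fold above the second-highest stage; below 0.1 everywhere is
not-expressed; a failed fold test (ties included — an exact tie can never
satisfy 1.5x) is shared. Sample structure is summarised by classical
(Torgerson) MDS on Euclidean distances in log10(piRPKM + 0.01) space,
reporting eigenvalue fractions over the positive spectrum. Synteny between
species is a purely geometric check: an anchor (two flanking genes per
species) is conserved iff every species has a cluster strictly inside the
open interval between its anchors.

# Target selection

A read associates with a transcript on >= 1 bp overlap with the genomic
span, introns included — intragenic-TE piRNAs are frequently intronic, so
exon-only association would miss precisely the biology of interest. Per
transcript the table carries sense/antisense/total piRPM, the unique-mapper
fraction and the TE-embedded fraction (copies overlapping TE segments that
intersect the transcript). Top targets are ranked by total piRPM (>= 70
piRPM, at most 500; sense-only and antisense-only rankings are a switch),
breed-reproducible targets are a set intersection, stages are united with
membership flags, and differential association keeps transcripts whose
pseudocounted ratio exceeds 2-fold. The 0.5-piRPM pseudocount makes
zero-association transcripts comparable; it is symmetric and small relative
to the 70-piRPM selection floor.

# The synthetic-data generator

`build_reference()` emits a random genome with planted TE copies (mutated,
5'-truncated copies of per-family consensus sequences), gene models with
exons and biotypes, rRNA/tRNA/miRNA loci whose sequences live on the
genome, and an FPKM table. `simulate_sample()` draws piRNA reads from
cluster specifications (multinomially across clusters by stage weight),
contaminant fragments from the ncRNA loci, and uniform genomic degradation
reads, appends the 3' adaptor, and records a truth row per read.

Three design choices deserve explanation:

* **Ping-pong pairs are anchored at 1U/10A-compatible genome sites.**
  A pair is primary + partner with 5' ends exactly 9 nt apart on opposite
  strands. Rather than overwriting read bases (which would break the
  exact-match mapping contract) the generator samples anchor positions
  where the genome already reads T at the primary 5' and A nine bases
  downstream; by complementarity both pair members then carry A at
  position 10 and the primary starts with U. Every read remains a literal
  genome substring.
* **Background reads avoid incidental d = 10 overlaps.** Non-pair cluster
  reads are rejection-sampled away from 5' positions that would create an
  exact 10-nt overlap with an existing opposite-strand read. This makes the
  planted ping-pong fraction exactly recoverable from the overlap spectrum.
  The flip side: in position-saturated clusters the background at d = 10 is
  suppressed below neighbouring overlap lengths, so a spectrum-wide z-score
  is only meaningful in sparse regimes (the suite evaluates it on a wide,
  sparse fixture).
* **Class separability is enforced, not assumed.** Degradation reads are
  redrawn until they neither equal any planted piRNA sequence nor occur
  inside any ncRNA locus; miRNA fragments are redrawn against rRNA/tRNA
  (and predicted ones against known precursors); planted piRNA sequences
  are checked against all ncRNA loci. Candidate recall and precision
  against the truth manifest are therefore exact, and each filter step
  removes exactly its planted contaminant count.

## Default study conditions

One 1 Mb genome (two chromosomes), seven TE families ("CR1-B".."CR1-H")
with ten copies each at 20% divergence — the high divergence matches an
ancient, degenerate repeat landscape and keeps exact 24-34-mers mostly
copy-specific, leaving a small multimapper fraction for the unique-mapper
audit. Twelve planted clusters (five TE blocks, three genic, four
intergenic) sit >= 12 kb apart, a density comparable to real genomes and
far enough that the gap detector cannot chain neighbours directly. Five
stage libraries (BC, PGC, E11G, E14G, AT) of 200,000 reads each: 190,900
cluster piRNAs plus 4000 rRNA + 2000 tRNA fragments, 2000 known and 1000
predicted miRNA reads, and 100 degradation reads (oxidised libraries are
piRNA-dominated; degradation is kept below one read per detector gap).
Group emission weights move from TE-dominant in BC (93%) through mixed
PGC/EG profiles to intergenic-dominant in AT (72%), with BC-, PGC-, EG- and
AT-specific clusters planted so every enrichment class is realisable;
AT-weighted clusters emit shorter reads (mean 25.5 nt vs 27.5 nt).
Per-stage library depth is configurable; the default (200 k) is a
round-number choice. Read lengths are normal, clipped to 24-34 nt; 5'-U
probability defaults to 0.9.

The noiseless cluster-recovery experiment uses the same reference and
cluster layout at 150,000 reads: the detector's 10 copies/kb floor means a
planted cluster is only detectable when its expected copies exceed density
x span, and at this depth the sparsest cluster (~0.1% share) draws about
34 copies/kb, safely above the floor.

## What the generator does not emulate

Sequencing errors and base qualities (all qualities constant); PCR
duplication; 5'-truncation heterogeneity of real CR1 insertions beyond a
single truncation draw; spliced (junction-spanning) piRNAs — the mapping
stage is deliberately unspliced and the generator never emits them;
stage-dependent ping-pong intensity (the pair fraction is per-cluster, not
per-stage, so the gradual 10A loss across development is only coarsely
mimicked by which clusters dominate a stage); chromatin or expression
coupling between TEs and their piRNAs. Green tests on this fixture
demonstrate algorithmic correctness under the stated statistical structure,
not performance on real libraries.

# Numerical and degenerate-input conventions

All internal coordinates are 0-based half-open; BED is written as-is, GTF
converts to 1-based inclusive (round-trip asserted). Empty candidate sets
raise explicit errors wherever a piRPM denominator would be zero. The
empty d = 10 subset is a typed signal. Zero-SD spectra give z = 0 or
signed infinity as described. Transcript extension errors out after 50
iterations as a safety net (growth is bounded by construction). Multimapper
ties, TE-family ties and stage-enrichment ties all break deterministically
(lexicographic; tie means shared). All randomness flows through explicit
seeds; identical seeds give byte-identical emitted files.

# Problem sizes used by the test suite

Unit fixtures use 150-300 kb genomes and 10^2-10^4 reads. The end-to-end
checks run the full default fixture (5 x 200 k reads) twice for the
byte-determinism comparison; signature-recovery fixtures use a ~100 kb
isolated cluster at 10-20 k reads; oracle comparisons use 20 random
10 kb genome instances (mapping), 10,000 random matrices (enrichment) and
1000 random tables (target selection). These sizes were chosen so the
statistical assertions (binomial confidence bands, +/- 0.02 recovery) are
sharp while a complete run stays comfortably interactive.
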