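---
title: "tripkit: models, assumptions and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tripkit: models, assumptions and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the science implemented by tripkit: the model
behind each pipeline stage, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, and the
design decisions taken where the underlying assay description leaves the
computation open.

## The assay and its statistic

TRIP-style reporter assays integrate a library of barcoded transgenes
into a cell population with the piggyBac transposase.  piggyBac inserts
at TTAA tetranucleotides and duplicates the target site, so every
integration is flanked by TTAA on both sides.  Each construct carries a
unique 18-nt barcode transcribed in its 3′UTR, immediately preceded by a
fixed 5-bp promoter index identifying which promoter drives it.  Three
amplicon libraries from one population measure each barcode's abundance
in gDNA (normalization), in cDNA (expression), and its genomic flank
(inverse-PCR mapping, bounded by DpnII digestion at GATC and
self-ligation).

The per-barcode activity is the ratio of within-library abundances:

$$a_i \;=\; \frac{e_i / E}{n_i / N} \quad[\text{a.u.}]$$

with $e_i, n_i$ the collapsed expression and normalization read counts
and $E, N$ the library totals.  Abundances are expressed as
parts-per-million within each library before the ratio; the assay only
defines "abundance", and ppm makes the statistic independent of
sequencing depth in both libraries (it is exactly invariant to scaling
either library, which the tests assert).  $a_i = 0$ iff the barcode has
no expression reads; the default silence threshold is exactly 0 ("no
expression evidence"), configurable because sequencing noise can produce
spurious single reads.

Reliability filtering keeps a transgene when all of

* `norm_count >= 5` — enough cells carry the insertion,
* `reads_r >= 10` — enough mapping reads,
* `freq1_r > 0.60` (strict) — a dominant single locus

hold.  `norm` is read here as the *collapsed raw read count* in the
normalization library, not a per-million value; the threshold of 5 on a
ppm scale would mean something entirely different at typical depths, and
raw counts are what an abundance cutoff naturally applies to.  The
boundary semantics (`>=`, `>=`, strict `>`) are encoded in one place and
exercised by boundary fixtures in the tests.

## Barcode extraction and error collapsing

Reads are `constant prefix + 5-bp index + 18-bp barcode (+ flank for
mapping reads)`.  Extraction anchors the constant prefix at the read
start allowing `anchorMismatch` substitutions (default 1) and cuts the
following 5 + 18 bases.  Rejections (`too_short`, `anchor_not_found`,
`ambiguous_base_in_barcode`) are returned as per-read data, never
raised, so read accounting stays exact: assigned + unassigned +
malformed always equals reads processed.

Index demultiplexing assigns the unique table entry within Hamming
distance `maxMismatch` (default 1).  The four default indexes
(`tacaa` → short EF-1α, `ccgag` → long EF-1α, `ctagt` → mPGK, `agctc` →
PGK) are pairwise at distance ≥ 4, so one mismatch is unambiguous; the
separation requirement `d >= 2*maxMismatch + 1` is validated and its
violation is a configuration error, not a silent misassignment.

Sequencing and PCR substitutions create low-count mutant barcodes one or
two changes away from a genuine one.  The assay description delegates
barcode identification to an external toolkit without specifying the
algorithm, so the collapse procedure is this package's own choice: a
**greedy directional collapse**, the standard scheme in UMI/barcode
error correction.  Within each (library, promoter) stratum, barcodes are
visited in (count descending, barcode ascending) order and merged into
the earliest already-genuine barcode with Hamming distance
≤ `maxDistance` (default 2) and mutant count < `ratioThreshold` × the
target's raw count (default 0.1).  The ratio test uses the target's raw
pre-merge count and the earliest qualifying target wins, which makes the
procedure fully deterministic; the tests verify it against an
independent all-pairs oracle and check count conservation and
idempotence of the resulting map.  Substitutions only — indels are a
non-goal, which is why distances are Hamming, not edit.  A barcode seen
under two promoter indexes is kept separately per index: the index is
part of the identity.

## Insertion mapping

The mapping stage is a deliberately small exact-k-mer seed-and-extend
aligner, sufficient for flanks on a synthetic genome and replaceable by
any external aligner for real assemblies (calls can be made from any
per-read alignment table).  A `KmerIndex` records every k-mer of both
strands (k = 20 by default, minimum 12); a flank seeds on its first
k-mer and each hit is extended over the full flank allowing
`maxMismatch` substitutions (default 2); all loci at the minimal
mismatch count are reported.

Coordinate convention: an insertion is the 1-based position of the first
T of the duplicated TTAA **on the plus strand**, whatever the transgene
orientation.  A plus-strand flank begins 4 bases past the TTAA
(`position = hit - 4`); a minus-strand flank reads leftwards from
`position - 1` (`position = hit + k`).  The DpnII site is retained: the
flank ends with the 4 GATC bases, since digestion and self-ligation keep
the site in the sequenced circle.  Flanks shorter than the seed length
(a GATC too close to the transposon end) are unusable; the simulator
flags such insertions `short_flank` in its truth table so tests can
condition on them.

Per barcode, the called locus is the (chrom, position, strand) supported
by most reads, ties broken lexicographically by chromosome, then
coordinate, then strand.  `reads_r` counts **all** mapping reads
carrying the barcode, including unalignable ones — this makes `freq1_r`
penalize chimeric and ambiguous inverse-PCR products rather than hiding
them.  Barcodes whose flanks never align produce no call and are
reported as residuals.

## Annotation

Gene elements are derived from GFF3 gene models: the promoter window is
−1000..+100 bp around the **distal** TSS (the transcript start furthest
upstream), in transcription orientation — 1101 bp per gene; 5′/3′UTRs,
exons and introns come from exon/CDS structures as unions over a gene's
transcripts.  Gene bodies run from the distal TSS to the TTS, so an
insertion "within a gene" includes the upstream kilobase.  Overlapping
labels are resolved at classification time by the fixed priority
**promoter > 5′UTR > 3′UTR > exon > intron**, with intergenic as the
fallback.  The priority is a design decision (nothing in the assay
description resolves overlaps): it makes the categories mutually
exclusive with regulatory regions dominant, and it is configurable.
When two genes tie at the winning priority the nearest-TSS gene is
reported.  Classification queries the single TTAA start coordinate, not
the 4-base interval — a point query cannot straddle two categories.

TSS/TTS distances are unsigned minima over *all* genes on the
chromosome, not just the host gene, computed independently for starts
and ends.  Chromatin types come from a BED4 segmentation; segments must
be non-overlapping (validated), coordinates falling in gaps or on absent
chromosomes are `unassigned` — mirroring real analyses where a
segmentation from a different assembly covers only part of the cohort.
Enrichment compares category proportions among all transgenes with the
`ceiling(0.10 n)` most active filtered ones and reports their ratio.
The rounding rule and the denominator (all filtered records) are fixed
here because the source material is ambiguous about both; the fraction
is a parameter.

## The motif matrix

Windows of `2W + 4` bases (W = 10 by default) are extracted around each
insertion — W upstream, the duplicated TTAA, W downstream — and
reverse-complemented for minus-strand insertions so all windows share
the transgene orientation.  Positions are numbered −W..−1, +1..+(W+4)
with no position 0, +1..+4 being the duplicated target site.  Per
position and base, the statistic is the pLogo-style binomial tail
against background rate $p$ (genome-wide mononucleotide frequencies of
the supplied FASTA by default):

$$\mathrm{lo}(j,b) = \begin{cases}
  -\log_{10} P(X \ge k) & k/n \ge p \\
  \;\;\,\log_{10} P(X \le k) & k/n < p
\end{cases}, \qquad X \sim \mathrm{Bin}(n, p)$$

computed in log space via `pbinom(log.p = TRUE)` for numerical
stability; tests require agreement with exact summation to 1e−9 for
n ≤ 30.  The sign always matches the direction of deviation.  Sites
whose window would cross a chromosome boundary are skipped and counted,
not errored.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions
under which the pipeline's statistical guarantees are demonstrated.
It emulates:

* a multi-chromosome genome of i.i.d. bases at a configurable GC
  fraction (default 0.45), guaranteeing ≥ 1 TTAA per kb on average;
* simple multi-exon gene models with UTR-bearing CDSs, and an
  11-state chromatin segmentation patterned on published CHO-K1
  chromatin types, with the three inactive states covering ~88 % of the
  genome;
* insertions placed uniformly at TTAA sites without replacement, random
  strand, promoter classes drawn from the 7:7:7:1 library mixing ratio,
  barcodes pairwise ≥ 5 apart (so collapse correctness is testable —
  real data offers no such guarantee and every threshold stays
  configurable);
* a configured silent fraction (default 0.5, exactly
  `round(f·n)` records at activity 0 — the cause of silencing is
  deliberately not modeled); active insertions draw log-normal activity
  (σ = 1) scaled by per-promoter factors (10, 1, 0.5, 0.3 for long
  EF-1α, short EF-1α, mPGK, PGK — ratios in the range reported for such
  promoters) and by a per-chromatin-state factor;
* clone abundances log-normal (σ = 1), standing in for a month of
  unselected polyclonal growth;
* per-insertion read counts Poisson with mean ∝ abundance
  (normalization, mapping) or abundance × activity (expression), scaled
  to the requested mean depth; i.i.d. per-base substitution errors
  (default 0.002); constant quality strings.

It does **not** model PCR jackpots or chimeras, indels, selection or
cell-cycle effects, primer sequences (reads are
`prefix + index + barcode (+ flank)` only — downstream code must not
depend on primer detail), or non-uniform insertion preference beyond
the TTAA requirement.  Passing tests therefore demonstrate correctness
of the computation under a clean error model, not robustness to every
real-library artifact; the `freq1_r` mechanism is the only handle for
chimeric reads.

Coordinates are 1-based inclusive internally and in GFF3; BED is
written and read 0-based half-open.  Mapping libraries are paired by
default (R1 index+barcode side, R2 flank, 75 bp reads); a single-end
concatenated mode exists for simplicity but leaves little flank in a
75-bp read.

## Problem sizes and seeds

The test suite exercises the full pipeline at 300 insertions on a
2 × 200 kb genome (mean depths 50/50/20, error rate 0.002), an
error-free run at 150 insertions for the exact-recovery and motif
invariants, and a null-calibrated run (all activities equal) for the
normalization identity; oracle comparisons use 1000 random loci
(element labeling), 20 random barcode tables (collapse) and exhaustive
small-n summation (binomial statistic).  All randomness is seeded; runs
are byte-deterministic for a fixed configuration, which the tests
assert file-by-file.

## Known limitations

* The aligner is exact-seed only: a sequencing error inside the first
  k bases of a flank loses that read (it still counts in `reads_r`).
  At the default error rate this costs ~4 % of reads, visible as
  `freq1_r` slightly below 1.
* Barcode collapse assumes substitution errors; an indel shifts the
  frame of the whole barcode and produces an unmergeable sequence.
* Gene-element derivation unions transcripts per gene; with many
  isoforms, UTR boundaries blur (the synthetic GFF uses one transcript
  per gene).
* Activity recovery degrades for barcodes with very low clone
  abundance, where Poisson noise dominates both counts — a property of
  the assay, not of the implementation.
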