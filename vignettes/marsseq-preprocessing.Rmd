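---
title: "Preprocessing MARS-seq experiments: model, parameters and design"
author: "marstools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preprocessing MARS-seq experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marstools)
```

# The problem

MARS-seq is a plate-based single-cell RNA-seq protocol: cells are
FACS-sorted into wells, lysed, and barcoded in two stages. Wells within
one amplification batch share a 4 nt *pool barcode* (PB) carried on
read 1; each well contributes a 7 nt *cell barcode* (CB) and every
molecule an 8 nt UMI, both on read 2. Read 1 additionally carries fixed
technical adapters: a 3 nt left adapter before the pool barcode and a
2 nt right adapter at the 3′ end, with the cDNA in between (66 nt on a
75 nt read 1).

Preprocessing such data means: checking the plate metadata, moving the
barcodes out of the sequence and into the read identity, aligning the
cDNA, and collapsing reads into molecule counts per well and gene.
Because droplet-oriented tooling assumes a single cell barcode on read 1,
the double-barcode layout also needs a conversion step before a
splice-aware CB/UMI counting aligner can be used for RNA velocity. This
package implements all of those stages as a library plus a thin command
line, with a seeded simulator that makes the complete path testable
offline against a known ground truth.

# Data model and stages

The central objects are S4 classes: `ReadLayout` (the byte-offset map of
the two mates), `ExperimentMetadata` (the three plate tables),
`Whitelist` (valid `PB‖CB` composites with well identities),
`StarsoloParams` (aligner barcode geometry) and `WellCountMatrix` (a
`SummarizedExperiment` of features × wells with demultiplexing tallies in
its metadata).

## Metadata validation as a checkpoint

`validateMetadata()` checks every invariant of the three tables —
barcode alphabet (`{A,C,G,T}` after upper-casing) and lengths (4/7 nt),
identifier uniqueness, referential integrity between sequencing batches,
amplification batches and wells, wells present for every batch, and
uniqueness of `(amp_batch, cell_barcode)` pairs. Violations are
*collected exhaustively* rather than raised one at a time, so a single
pass over the report fixes all mistakes; `runPipeline()` then converts a
failed report into a hard stop before any read is touched. The report is
deterministic and order-independent: permuting input rows changes only
the row indices in messages, never the set of error codes. Spreadsheet
workbooks are accepted via `convertWorkbook()`, which only trims
whitespace — canonical column names are defined by this package's
documentation, with a case-insensitive alias map for headers in common
use, since no authoritative schema exists for the legacy dialects.

## Read labeling

`labelReads()` slices at fixed offsets: PB = R1[3..6], cDNA from
position 7 to the third-from-last base, CB = R2[0..6], UMI = R2[7..14]
(0-based half-open internally; 1-based only where rendered for the
aligner). The final two bases of read 1 are always trimmed as the right
adapter; treating them as technical rather than insert is what makes the
effective cDNA 66 nt on a 75 nt read. Labels are written into the read
name as `<id>:<PB>:<CB>:<UMI>` (delimiter configurable, since SAM
consumers tokenize names differently), which keeps the barcode
information intact through any aligner.

Two filters discard pairs, each tallied by reason so that
`n_input = n_kept + sum(discarded)` always holds: `too_short` when a
mate cannot hold its segments, and `low_quality_barcode` when more than
`maxLowQualBases` (default 1) of the 19 barcode bases fall below Phred
`minBarcodeQual` (default 20). The defaults reflect where errors matter:
a miscalled barcode base silently reassigns a molecule to another well,
whereas cDNA quality only affects mappability, which the aligner already
handles. Optional 3′ poly-A trimming (runs of ≥ 10 A) is off by default.
Labeling is reversible for kept reads — the trimmed left adapter is
retained alongside the segments — which is what the round-trip tests
exercise.

`splitFastq()` streams records into chunks of 4 000 000 reads by default
(the conventional bound for memory-restricted aligners), passing bytes
through untouched and reporting a truncated trailing record with its
byte offset.

## 10X conversion, whitelist and aligner geometry

`convertReads()` rewrites each kept pair as `R1 = PB‖CB‖UMI` (19 nt) and
`R2 = cDNA`, with quality strings permuted alongside their bases, so the
conversion is lossless and invertible (`invertConvertedReads()`).
`buildWhitelist()` enumerates, per amplification batch, the pool barcode
concatenated with each well's cell barcode; the whitelist spans the
whole experiment because one aligner run consumes one whitelist file. A
collision — two wells mapping to one 11-mer — is a plate-design error
and aborts with both well identities rather than silently merging wells.
`starsoloParams()` derives the `CB_UMI_Simple` geometry from the layout
(composite barcode of 11 at position 1, UMI of 8 at position 12 for the
default layout) and renders the flag string; requesting the `Velocyto`
feature set is what yields spliced/unspliced matrices downstream. The
aligners themselves are deliberately external: commands are rendered
into `commands.sh`, never executed.

## Demultiplexing and UMI collapse

`countReads()` consumes alignments whose names carry the label.
Exclusion is staged and fully tallied — unmapped, below-MAPQ, ambiguous
(multi-gene), featureless, unknown-feature, unassigned-barcode — so the
conservation identity `n_input = counted + excluded` is checkable in
every run report. Barcode assignment is strict whitelist membership by
default (`maxBcDist = 0`), because validity is defined by the whitelist;
with `maxBcDist = 1` a non-member is rescued only when *exactly one*
entry sits at Hamming distance 1 — a tie is evidence of nothing and
stays unassigned. `N` bases never match exactly and count as one
mismatch.

Per (well, feature), `collapseUmis()` supports two models:

* **exact** (default): distinct UMI strings. This is the plainest
  reading of UMI counting and the mode under which an error-free
  simulation reproduces its ground truth exactly.
* **directional**: merge `u → v` allowed when the two UMIs differ at one
  position and `count(u) ≥ 2·count(v) − 1`; molecules are the connected
  components reached by following merges from high-count UMIs downward.
  Processing order is deterministic (count descending, then sequence as
  tie-break), so equal-count neighbours merge into one component
  regardless of input order. Directional counts are provably ≤ exact
  counts, and the tests assert this monotonicity per cell.

MAPQ is not filtered by default (threshold 0); multi-mapper policy is
left to the aligner's flags. Gene identity is consumed from a per-read
tag (`GX`) when present; for SAMs lacking tags an exon-overlap annotator
(strand-aware by default, 1-based inclusive GTF coordinates) is
provided, with reads overlapping two genes marked ambiguous.

## Reference augmentation

`buildReference()` appends spike-in records after the genome records —
order and sequence content preserved — and adds, per spike-in,
`gene`/`transcript`/`exon` lines spanning positions 1..length on the
`+` strand with `gene_id = transcript_id`. Spike-ins are synthetic
unspliced transcripts, hence the single-exon annotation. The consortium
set of 92 controls is supplied by the user as FASTA or the tab-delimited
definition table (`readErccSet()`); `erccSyntheticSet()` generates a
deterministic synthetic stand-in with the same cardinality and id style
for offline work, and is labelled as such.

# The simulator: what it emulates and what it does not

`simulateExperiment()` generates every artifact the stages consume, from
one seed, byte-reproducibly (R's gzip stream stores no timestamp, so
identical seeds give identical file hashes). Its defaults — 2
amplification batches × 8 wells, 20 genes + 3 spike-ins, 200 reads per
well, 75 nt read 1, error rates 0 — are the standing study conditions of
the test suite; the acceptance checks run at exactly these settings.

Design choices, made once:

* Barcodes are drawn with pairwise Hamming distance ≥ 2 within each role,
  as real plate designs do, so single errors cannot convert one valid
  barcode into another; an infeasible request errors rather than
  degrading.
* Molecules are planted per well and reads drawn from them with mean
  multiplicity `duplicationRate = 2`, a typical plate-based duplication
  level; without duplication UMI collapse would be vacuous. Ground truth
  is the number of distinct *sequenced* (well, feature, UMI) triples.
* Errors are substitutions only, applied per base to barcode and UMI
  positions at the configured rates. Indels are excluded by design: the
  layout slices at fixed offsets, and indel robustness is explicitly out
  of scope.
* Fixed adapters default to `TGA`/`TT`; any fixed value satisfies the
  layout contract and both are configurable.
* An oracle SAM of perfect, gene-tagged alignments is emitted so that
  demultiplexing is testable without running an aligner.

What the simulator does *not* model, and hence what passing tests do not
show: realistic expression distributions (counts are planted uniformly,
not drawn from a negative-binomial), gene-length or positional bias,
cDNA sequencing errors or unmappable reads, chimeras, and ambient
contamination between wells. Pipeline correctness on the simulator
therefore demonstrates the bookkeeping — slicing, assignment, collapse,
conservation — not biological fidelity of any particular dataset.

# Numerical and degenerate-case choices

* Quality decoding assumes Phred+33; the low-quality rule counts bases
  strictly below the threshold.
* Empty inputs are defined, not errors: zero reads give empty FASTQ
  files and an all-zero truth matrix spanning the full well × feature
  grid; an empty spike-in set leaves the reference unchanged; an empty
  UMI multiset collapses to 0.
* The directional tie-break (count descending, then lexicographic)
  makes collapse deterministic for any input ordering.
* Sparse matrices use the MatrixMarket triplet exchange layout
  (`matrix.mtx` + `features.tsv` + `barcodes.tsv`), features × wells,
  with a dense TSV added for small matrices.

# Problem sizes in the test suite

The suite runs entirely on generated data: the end-to-end round trip and
the noisy-recovery check use the default 3 200-read configuration;
conservation is property-tested on a 100 000-read random stream;
conversion invertibility on 10 000 random labeled reads; barcode
assignment against a brute-force Hamming scan over a 4 096-entry
whitelist; and exact-mode totals against a distinct-triple oracle on
instances up to 1 000 reads. These sizes were chosen to exercise every
code path at plate scale while keeping the default test run fast.

# Known limitations

* Aligners are out of scope: the package emits their parameter strings
  and consumes SAM, nothing more. Spliced/unspliced classification
  happens in the external aligner's velocity feature.
* Barcode correction is limited to unique Hamming-1 rescue; no
  quality-weighted or frequency-weighted posterior correction.
* The workbook reader accepts `.xlsx` only, and the simulator emits
  metadata as TSV.
* Well identities are FACS-defined; there is deliberately no
  cell-calling or empty-droplet inference.
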