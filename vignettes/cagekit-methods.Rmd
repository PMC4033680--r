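---
title: "cagekit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cagekit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagekit)
```

cagekit implements the computational core of a CAGE (cap analysis of
gene expression) processing pipeline as plain R functions over plain
data frames, so that every stage can be run, inspected and tested in
isolation. This vignette explains the models and conventions behind
each stage, the parameters that matter, and the choices made where the
design was genuinely open.

## Coordinates and data carriers

All internal coordinates are 0-based half-open (the BED convention);
1-based formats (SAM/BAM, GRanges) are converted at the I/O boundary.
The central record is the CTSS — one transcription start site as
`(chrom, pos, strand, count)` with `pos` a single base. A plus-strand
alignment contributes its leftmost aligned base, a minus-strand
alignment its rightmost (`end − 1`); this is forced by the CAGE
chemistry, which sequences from the capped 5' end. Soft-clipped bases
are excluded from the aligned span (the SAM adapter uses the CIGAR
reference span), so a clipped 5' end shifts the CTSS accordingly. Two
known simplifications: no correction for the template-switching "extra
G" sometimes added at the first base, and each supplied alignment
counts once — multi-mapper deduplication or weighting is left to the
caller, since the toolkit does not control the upstream mapper.

## Demultiplexing and trimming

Pooled reads are laid out `[barcode][CAGCAG][tag]`. A read is assigned
to the unique sample whose barcode matches the read prefix within
`max_mismatch` mismatches, and the linker that follows must match
within the same budget; otherwise the read lands in `unassigned`,
untrimmed. The default `max_mismatch = 0` is deliberately
conservative: with error-free fixture data assignment is then exact,
and on real data a zero-tolerance default avoids cross-sample bleed at
the cost of yield. Barcode sets are validated up front (equal lengths,
pairwise Hamming distance > 2·`max_mismatch`) so assignment can never
be ambiguous. For paired-end input, read 1 carries the barcode and
decides the assignment; the mate travels unmodified. N-containing
reads are removed *after* trimming, so an `N` inside a to-be-discarded
barcode does not cost a read.

## Contaminant filtering

rRNA and artifact reads are removed by deterministic seed-and-extend,
ungapped matching: a read is flagged when it shares an exact k-mer
(default `kmer_length = 12`) with a reference and the shared diagonal
supports a window of at least `min_match_length = 20` bases with
mismatch fraction at most `max_mismatch_fraction = 0.1`. The window is
the *longest* feasible one containing the seed, found by exhaustive
scan over the diagonal — this makes the removed set monotone in the
mismatch tolerance, which the property tests rely on. rRNA matching
also searches the reverse complement of each reference (rRNA
contamination is strand-agnostic); artifact matching does not, because
artifact libraries are defined on the read strand. These defaults are
the toolkit's own calibration for desk-scale, deterministic behaviour;
a full library-composition error model (as in dedicated artifact
removers) is intentionally out of scope.

## Peak calling by parametric density clustering

For a density parameter $d$, score a genomic segment by
$\mathrm{tags} - d \cdot \mathrm{span}$. The clusters at level $d$ are
the maximal scoring segments; as $d$ grows, clusters shrink and split,
producing a nested hierarchy. Each cluster is maximal over a density
interval $(d_{\min}, d_{\max})$, and the ratio
$d_{\max}/d_{\min}$ — its *stability* — measures how robustly it stands
out from its surroundings. The implementation is the standard
recursion: for the current site range, the prefix or suffix removal of
minimum density (tags per base of removed span) determines the
enclosing cluster's $d_{\max}$ and splits the range; children inherit
that density as $d_{\min}$. Ties in the minimum break density go to
the leftmost breakpoint, for determinism. Densities use the genomic
span `end − start` as denominator. Single-site clusters have no proper
prefix or suffix, so their $d_{\max}$ (and any stability with
$d_{\min} \le 0$, e.g. the root) is capped at a sentinel constant of
`1e9`, which keeps the output numeric and sorts above any real
stability.

The test suite verifies the recursion against an independent
brute-force oracle: Ruzzo–Tompa maximal-scoring-segment extraction at a
density sampled inside every interval of the critical-density grid,
collecting each segment's appearance range. The two agree exactly on
hundreds of random instances; the only convention-driven difference is
that the recursion also reports single sites that are never maximal on
their own (their merge density exceeds their count), which the sentinel
convention covers.

Peak selection keeps clusters of length at most 200 bp with stability
strictly greater than 2 — the published operating point for promoter
peaks — then reduces nested survivors to the outermost qualifying
clusters, so reported peaks never overlap. Keeping the outermost
survivor (rather than the most stable) is the toolkit's choice: it
preserves total tag counts within a locus and keeps peak boundaries
conservative. An optional minimum tag count is exposed but off by
default. Note one consequence of de-nesting: tightening a threshold
can *increase* the peak count (an outer survivor disappears and
exposes several children), so the guaranteed monotonicity is coverage
containment, not count.

## Hierarchical annotation

Gene models (BED12; `thickStart/thickEnd` as CDS) are decomposed into
six category interval sets, in fixed priority order: 100 bp upstream
of the transcript start (strand-aware), 5′ UTR exon, coding exon,
3′ UTR exon, intron, 100 bp downstream. Intervals are clipped at
position 0 and merged within a category. Each CTSS accrues its full
count to the first category containing it; anything left is
intergenic — so category counts always sum to the input count.
Intersection ignores the CTSS strand by default, matching plain
interval intersection with `intersectBed`-style tooling; a
strand-aware mode is available as a flag. Non-coding models
(`cds_start == cds_end`) contribute all exonic bases to a single exon
class carried in the 5′ UTR slot, so promoter-proximal signal on
non-coding genes is not misclassified as intergenic. The hierarchy
order is applied globally: when two genes overlap, a higher-priority
category of one gene beats a lower-priority category of the other,
which is what a single ordered intersection pass produces.

## The expression store

The store keeps, per (chromosome, strand), a strictly increasing
position array with CSR row pointers into arrays of sample indices and
counts. BED6 queries locate the position range by binary search
(`O(log n + hits)`) and sum per sample; stranded intervals restrict to
the matching strand, unstranded (`.`) intervals sum both. Overlapping
promoter intervals are merged before promoter-fraction computation so
no tag is double-counted. Normalization is counts-per-million — the
natural per-library scaling for tag counts; raw counts remain
available. Persistence is a single text file: a JSON header (samples,
library sizes, block table) followed by four lines of integers per
block; a reloaded store is bit-identical to the original, which the
round-trip tests assert with `identical()`.

## QC and sample clustering

A library passes QC when its rRNA fraction is strictly below 0.10 and
its mapping rate strictly above 0.70, the published acceptability
thresholds; both are parameters of `qc_thresholds()`. Sample
similarity is Pearson correlation computed on `log(x + 1)`-transformed
normalized expression — raw-count correlation is dominated by the few
strongest peaks; a raw mode exists for comparison. Samples are
clustered by average-linkage agglomeration on distance $1 - r$.
Bootstrap support resamples peaks (rows) with replacement, reclusters,
and reports for each original node the fraction of replicates in which
the same sample set reappears (the plain bootstrap probability, BP).
Multiscale/approximately-unbiased p-values are intentionally not
implemented; BP is sufficient for the fixture-scale questions the
toolkit answers, and the clustering can always be exported to
specialised packages. Within a bootstrap replicate a resampled column
can be constant; its correlations are set to 0 rather than aborting
the replicate, a documented tolerance that cannot occur on the
original matrix (there a constant column is an error naming the
sample).

## Workflow engine

Units wrap one command template with named, format-tagged input and
output slots and typed parameters with defaults (e.g. a SAM-to-BAM
unit, or a mapper unit with `error-rate` defaulting to 0.04). Format
tags are opaque strings compared for equality when edges are wired —
no content sniffing. Execution is sequential in topological order
(local execution keeps provenance simple; cluster submission is out of
scope); a step with several inputs runs only after all producers
finish. An output slot marked *multi* emits a file set, and the
downstream subgraph is replicated once per emitted file, in sorted
name order; single bindings broadcast across replicas. A nonzero exit
halts only the affected branch, recording dependents as skipped.
Every executed instance yields a provenance record — resolved command,
wall-clock times, exit code, input/output file sizes, captured
stdout/stderr — written as JSON next to an HTML report and a YAML copy
of the workflow itself. Re-importing that copy and re-executing on the
same inputs reproduces deterministic outputs byte-identically, which
is the engine's reproducibility contract and is asserted in the tests.
Intermediate files are kept by default; deletion is opt-in so a
finished run stays inspectable.

## The synthetic-data generator

The fixture generator emulates the structure of a multiplexed CAGE
run, not its noise spectrum. A uniform-random genome (default two
chromosomes, 100 kb and 60 kb) carries non-overlapping gene models
with 1–4 exons and randomized CDS bounds, spaced so that 100 bp flanks
never collide. Reads are `barcode + CAGCAG + 25 bp tag`; tags are
drawn from a category mix (defaults: 15 % upstream, 40 % 5′ UTR, 15 %
CDS, 5 % 3′ UTR, 10 % intron, 3 % downstream, 12 % intergenic — a
promoter-dominated profile typical of polyA+ CAGE libraries), with
promoter-proximal tags jittered geometrically within 10 bp of the
annotated TSS so density clustering has sharp peaks to find.
Contaminant reads are allocated by rounded per-sample quotas rather
than sampled, so planted fractions are exact and the corresponding
tests need no tolerance; ambiguous-base injection, by contrast, is
Bernoulli per read, and its test uses a binomial interval. Contaminant
reference sequences are drawn from a seed stream offset from the
genome's so a shared seed cannot make the rRNA reference a copy of the
genome. With `group_effect > 1`, samples split into two groups that
prefer opposite halves of the gene set by that fold change; at the
default study conditions (6 samples, 10,000 reads, 6-fold effect) the
group split is recovered with bootstrap support ≥ 0.95. Truth placement
(`place_reads`) stands in for an external mapper: every tag maps
exactly at its true locus and contaminants are unmapped, so
mapping-rate arithmetic is exact. What passing these tests does *not*
show: robustness to mapper ambiguity, quality-score error profiles,
PCR duplication, or real promoter shape distributions — the generator
has none of these.

## Problem sizes and determinism

The shipped tests run the oracle-equivalence checks on 200 random
instances of up to 60 sites (peak calling) and 200 random intervals
(store queries), demultiplex 10,000-read fixtures, and bootstrap with
100 replicates — sizes chosen so the whole suite completes in a few
minutes on one core while still exercising every contract. All
randomness flows through R's Mersenne-Twister RNG under explicit
seeds; reruns are bit-reproducible on any platform with the same R
version.
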