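# cagekit

An R toolkit for processing and analysing CAGE (cap analysis of gene
expression) sequencing data. CAGE captures the 5' ends of capped RNAs:
after mapping, the 5'-most base of each read marks a transcription start
site (TSS), and the read count at that base measures promoter activity.
cagekit covers the data-processing core between a pooled FASTQ and a
clustered multi-sample expression matrix, for wet-lab and computational
groups who need a scriptable, fully testable alternative to a web
pipeline:

* **Demultiplexing and trimming** — pooled reads laid out as
  `[barcode][CAGCAG linker][tag]` are split by barcode (configurable
  mismatch tolerance, paired-end aware) and trimmed to the tag;
  reads containing ambiguous bases (`N`) are removed.
* **Contaminant filtering** — deterministic seed-and-extend matching
  removes reads derived from ribosomal RNA (strand-agnostic) and from
  artifact/primer-dimer sequences.
* **CTSS extraction** — alignments (SAM/BAM/BED) are reduced to CAGE
  transcription start sites: plus-strand reads contribute their start,
  minus-strand reads their `end − 1`; counts per site are aggregated.
* **Peak calling** — parametric density clustering. For a density
  parameter *d*, a cluster is a maximal scoring segment under
  *score = tags − d·span*; sweeping *d* yields a nested hierarchy in
  which each cluster is maximal over a density range
  (*d*<sub>min</sub>, *d*<sub>max</sub>). Its *stability*
  *d*<sub>max</sub>/*d*<sub>min</sub> measures robustness. Peaks are the
  outermost clusters of length ≤ 200 bp with stability > 2.
* **Hierarchical annotation** — each CTSS is assigned to exactly one
  category in priority order: 100 bp upstream, 5′ UTR exon, coding
  exon, 3′ UTR exon, intron, 100 bp downstream, else intergenic.
* **Expression store** — a compressed sparse row (CSR) database of
  per-position, per-sample counts, queryable with BED6 intervals by
  binary search, with counts-per-million normalization and per-library
  promoter fractions.
* **QC and sample clustering** — base composition, read-survival bar
  graphs, frequent sequences, pass/fail verdicts (rRNA < 10 %, mapping
  rate > 70 %), Pearson correlation on log-transformed expression,
  average-linkage dendrograms with bootstrap probabilities and a
  correlation heatmap.
* **Workflow engine** — command-template units with typed input/output
  slots (e.g. `samtools view -bSo [output] [input]`), DAG execution
  with fan-out over emitted file sets, per-step provenance (resolved
  command, timings, exit codes, file sizes, captured output), an HTML +
  JSON run report, and an embedded workflow copy that re-executes to
  byte-identical outputs.
* **Synthetic fixtures** — a deterministic generator for toy genomes,
  gene models and barcoded reads with planted contaminants and a full
  truth table, so every stage is testable without downloads.

## Worked example

```r
library(cagekit)

genome <- make_toy_genome(seed = 1)
models <- make_gene_models(genome, n_genes = 20, seed = 1)
barcodes <- c(liver = "ACTG", brain = "CGTA")
sim <- simulate_cage_reads(genome, models, barcodes, n_reads = 2000,
                           rrna_fraction = 0.05, seed = 1)

specs <- barcode_specs(names(barcodes), barcodes)
bins <- split_by_barcode(sim$reads, specs)
#> reads per bin: liver=1000 brain=1000 unassigned=0

flt <- filter_rrna(bins$liver, sim$rrna_ref)
#> liver rRNA fraction: 0.050        (exactly the planted 5 %)

ctss <- extract_ctss(place_reads(sim, flt$kept$id))
#> liver CTSS sites: 531   tags: 930

peaks <- select_peaks(paraclu_all(ctss))
#> peaks (length <= 200, stability > 2): 315
head(peaks[peaks$n_sites > 3, c("chrom","start","end","total_count","stability")], 3)
#>    chrom start  end total_count stability
#> 10  chr1  1628 1636          15    53.500
#> 36  chr1  6040 6051          57    78.375
#> 46  chr1  8358 8370          16     9.800
```

The 1000 liver reads demultiplex with zero losses (no sequencing errors
were injected), the rRNA filter removes exactly the 50 planted rRNA
reads, and peak calling condenses the 531 TSS positions into 315
promoter-like peaks; the 8 bp peak at chr1:1628 collects 15 tags and is
maximal over a 53-fold density range.

A command-line front end wrapping the same functions ships in
`inst/cli/cagekit.R` (subcommands `demux`, `filter`, `ctss`, `peaks`,
`annotate`, `tome-build`, `tome-query`, `promoter-fraction`, `run`).

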