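Package: cagekit
Title: Processing and Analysis of CAGE 5'-End Sequencing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A scriptable toolkit for the core processing steps of cap
    analysis of gene expression (CAGE) data: barcode demultiplexing and
    linker trimming of pooled 5'-end reads, removal of ribosomal RNA and
    artifact sequences, extraction of CAGE transcription start sites
    (CTSS) from alignments, parametric density clustering of CTSS into
    peaks, hierarchical single-assignment annotation of tags against gene
    models, a compressed sparse row expression store queryable by BED6
    intervals, quality-control summaries with sample clustering and
    bootstrap support, and a small provenance-tracking workflow engine.
    A deterministic synthetic-data generator produces toy genomes, gene
    models and barcoded reads with truth tables so every stage can be
    exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
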