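# shared fixture helpers: everything is generated in code at test time

tmp_lines <- function(lines, ext = "") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

default_barcodes <- function(k = 4L) {
  bc <- c("ACTG", "CGTA", "GTAC", "TACG", "AGGA", "GAAG")[seq_len(k)]
  setNames(bc, paste0("s", seq_len(k)))
}

# a small complete simulated run: genome, models, reads, truth
small_sim <- function(seed = 1L, n_reads = 1000L, k = 4L, ...) {
  genome <- make_toy_genome(seed)
  models <- make_gene_models(genome, 16L, seed)
  barcodes <- default_barcodes(k)
  sim <- simulate_cage_reads(genome, models, barcodes, n_reads = n_reads,
                             seed = seed, ...)
  list(genome = genome, models = models, barcodes = barcodes,
       specs = barcode_specs(names(barcodes), barcodes), sim = sim)
}

# random sorted CTSS on one chromosome strand
random_ctss <- function(n, max_pos = 500L, max_count = 20L,
                        chrom = "chr1", strand = "+") {
  pos <- sort(sample.int(max_pos, n))
  data.frame(chrom = chrom, pos = pos, strand = strand,
             count = sample.int(max_count, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# random multi-chromosome CTSS libraries for store tests
random_libraries <- function(n_samples, n_sites, chroms = c("chr1", "chr2"),
                             max_pos = 2000L) {
  libs <- lapply(seq_len(n_samples), function(s) {
    chrom <- sample(chroms, n_sites, replace = TRUE)
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    pos <- sample.int(max_pos, n_sites, replace = TRUE)
    df <- data.frame(chrom = chrom, pos = pos, strand = strand,
                     count = sample.int(50L, n_sites, replace = TRUE),
                     stringsAsFactors = FALSE)
    df <- df[!duplicated(paste(df$chrom, df$pos, df$strand)), , drop = FALSE]
    df
  })
  setNames(libs, paste0("lib", seq_len(n_samples)))
}
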