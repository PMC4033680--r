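gene_df <- function(chrom = "chr1", tx_start, tx_end, strand = "+",
                    cds_start, cds_end, exon_starts = NULL,
                    exon_ends = NULL, name = "g1") {
  df <- data.frame(chrom = chrom, tx_start = tx_start, tx_end = tx_end,
                   name = name, score = 0, strand = strand,
                   cds_start = cds_start, cds_end = cds_end,
                   stringsAsFactors = FALSE)
  df$exon_starts <- list(if (is.null(exon_starts)) tx_start else exon_starts)
  df$exon_ends <- list(if (is.null(exon_ends)) tx_end else exon_ends)
  df
}

gr_to_bed0 <- function(gr) {
  if (length(gr) == 0L) return(matrix(0L, 0L, 2L))
  unname(cbind(BiocGenerics::start(gr) - 1L, BiocGenerics::end(gr)))
}

test_that("single-exon coding gene yields the canonical category layout", {
  m <- gene_df(tx_start = 1000L, tx_end = 2000L, cds_start = 1200L,
               cds_end = 1800L)
  h <- build_hierarchy(m, flank = 100L)
  expect_equal(gr_to_bed0(h$upstream), cbind(900L, 1000L))
  expect_equal(gr_to_bed0(h$utr5), cbind(1000L, 1200L))
  expect_equal(gr_to_bed0(h$cds), cbind(1200L, 1800L))
  expect_equal(gr_to_bed0(h$utr3), cbind(1800L, 2000L))
  expect_equal(nrow(gr_to_bed0(h$intron)), 0L)
  expect_equal(gr_to_bed0(h$downstream), cbind(2000L, 2100L))
})

test_that("minus-strand gene mirrors upstream/downstream and UTRs", {
  m <- gene_df(tx_start = 1000L, tx_end = 2000L, strand = "-",
               cds_start = 1200L, cds_end = 1800L)
  h <- build_hierarchy(m, flank = 100L)
  expect_equal(gr_to_bed0(h$upstream), cbind(2000L, 2100L))
  expect_equal(gr_to_bed0(h$downstream), cbind(900L, 1000L))
  expect_equal(gr_to_bed0(h$utr5), cbind(1800L, 2000L))
  expect_equal(gr_to_bed0(h$utr3), cbind(1000L, 1200L))
})

test_that("flanks are clipped at position zero and flank must be positive", {
  m <- gene_df(tx_start = 40L, tx_end = 1040L, cds_start = 240L,
               cds_end = 840L)
  h <- build_hierarchy(m, flank = 100L)
  expect_equal(gr_to_bed0(h$upstream), cbind(0L, 40L))
  expect_error(build_hierarchy(m, flank = 0L), "> 0")
})

test_that("introns are transcript span minus exons", {
  m <- gene_df(tx_start = 0L, tx_end = 1000L, cds_start = 100L,
               cds_end = 900L, exon_starts = c(0L, 400L),
               exon_ends = c(200L, 1000L))
  h <- build_hierarchy(m)
  expect_equal(gr_to_bed0(h$intron), cbind(200L, 400L))
})

test_that("a CTSS in two categories counts once, in the higher-priority one", {
  # two genes overlap: CTSS falls in gene A's utr5 and gene B's intron
  a <- gene_df(tx_start = 1000L, tx_end = 2000L, cds_start = 1500L,
               cds_end = 1900L, name = "A")
  b <- gene_df(tx_start = 500L, tx_end = 3000L, cds_start = 600L,
               cds_end = 2900L, exon_starts = c(500L, 2800L),
               exon_ends = c(700L, 3000L), name = "B")
  h <- build_hierarchy(rbind(a, b))
  ctss <- data.frame(chrom = "chr1", pos = 1100L, strand = "+", count = 7L)
  counts <- annotate_ctss(ctss, h)
  expect_equal(unname(counts[["utr5"]]), 7)
  expect_equal(sum(counts), 7)
})

test_that("empty hierarchy sends everything to intergenic", {
  h <- build_hierarchy(gene_df(tx_start = 1000L, tx_end = 2000L,
                               cds_start = 1200L, cds_end = 1800L)[0L, ])
  ctss <- data.frame(chrom = "chr9", pos = 5L, strand = "+", count = 3L)
  expect_equal(unname(annotate_ctss(ctss, h)[["intergenic"]]), 3)
})

test_that("category counts are conserved over random fixtures", {
  for (seed in 1:10) {
    set.seed(seed)
    genome <- make_toy_genome(seed, c(chr1 = 50000L))
    models <- make_gene_models(genome, 8L, seed)
    h <- build_hierarchy(models)
    ctss <- data.frame(chrom = "chr1",
                       pos = sample.int(49000L, 200L),
                       strand = sample(c("+", "-"), 200L, replace = TRUE),
                       count = sample.int(10L, 200L, replace = TRUE),
                       stringsAsFactors = FALSE)
    ctss <- ctss[!duplicated(paste(ctss$pos, ctss$strand)), , drop = FALSE]
    counts <- annotate_ctss(ctss, h)
    expect_equal(sum(counts), sum(ctss$count))
  }
})

test_that("planted per-category CTSS are recovered exactly", {
  sm <- small_sim(seed = 55, n_reads = 3000L, rrna_fraction = 0,
                  artifact_fraction = 0)
  h <- build_hierarchy(sm$models)
  lib <- extract_ctss(place_reads(sm$sim))
  counts <- annotate_ctss(lib, h)
  planted <- table(sm$sim$truth$category)
  for (cat in names(planted)) {
    expect_equal(unname(counts[[cat]]), unname(as.numeric(planted[[cat]])),
                 label = cat)
  }
})

test_that("reflecting a gene swaps upstream and downstream fractions", {
  m_plus <- gene_df(tx_start = 1000L, tx_end = 2000L, cds_start = 1200L,
                    cds_end = 1800L, strand = "+")
  m_minus <- gene_df(tx_start = 1000L, tx_end = 2000L, cds_start = 1200L,
                     cds_end = 1800L, strand = "-")
  # sites 50 bases 5' of tx start and 50 bases 3' of tx end
  ctss <- data.frame(chrom = "chr1", pos = c(950L, 2050L),
                     strand = c("+", "+"), count = c(10L, 4L),
                     stringsAsFactors = FALSE)
  up_plus <- annotate_ctss(ctss, build_hierarchy(m_plus))
  up_minus <- annotate_ctss(ctss, build_hierarchy(m_minus))
  expect_equal(unname(up_plus[["upstream"]]), 10)
  expect_equal(unname(up_plus[["downstream"]]), 4)
  expect_equal(unname(up_minus[["upstream"]]), 4)
  expect_equal(unname(up_minus[["downstream"]]), 10)
})

test_that("annotation tables normalize per library and flag empty ones", {
  one <- setNames(c(0, 0, 0, 0, 0, 0, 120), c(
    "upstream", "utr5", "cds", "utr3", "intron", "downstream", "intergenic"))
  half <- setNames(c(50, 0, 0, 0, 50, 0, 0), names(one))
  zero <- setNames(numeric(7), names(one))
  tbl <- annotation_table(list(a = one, b = half, z = zero))
  expect_equal(tbl$frac.intergenic[1L], 1.0)
  expect_equal(tbl$frac.upstream[2L], 0.5)
  expect_equal(tbl$frac.intron[2L], 0.5)
  fr <- as.matrix(tbl[, grep("^frac\\.", names(tbl))])
  expect_equal(unname(rowSums(fr[1:2, ])), c(1, 1), tolerance = 1e-9)
  expect_equal(tbl$note, c("", "", "zero_tags"))
  expect_equal(unname(rowSums(fr))[3L], 0)
})

test_that("shrinking a higher-priority category never shrinks lower ones", {
  m <- gene_df(tx_start = 1000L, tx_end = 2000L, cds_start = 1200L,
               cds_end = 1800L)
  set.seed(77)
  ctss <- data.frame(chrom = "chr1", pos = sample(900:2099, 120L),
                     strand = "+", count = 1L, stringsAsFactors = FALSE)
  h_full <- build_hierarchy(m, flank = 100L)
  h_small <- build_hierarchy(m, flank = 10L)  # smaller upstream/downstream
  full <- annotate_ctss(ctss, h_full)
  small <- annotate_ctss(ctss, h_small)
  expect_true(all(small[c("utr5", "cds", "utr3", "intron", "intergenic")] >=
                    full[c("utr5", "cds", "utr3", "intron", "intergenic")]))
})
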