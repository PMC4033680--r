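reads_of <- function(seqs) {
  data.frame(id = sprintf("r%d", seq_along(seqs)), sequence = seqs,
             quality = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
}

test_that("base composition counts per position and conserves read counts", {
  bc <- base_composition(reads_of(rep("AC", 10L)))
  expect_equal(unname(bc[1L, "A"]), 10L)
  expect_equal(unname(bc[2L, "C"]), 10L)
  expect_equal(sum(bc[1L, ]), 10L)

  uneq <- base_composition(reads_of(c("ACGT", "AC")))
  expect_equal(sum(uneq[1L, ]), 2L)
  expect_equal(sum(uneq[3L, ]), 1L)   # only the longer read reaches here

  # barcode + linker prefix is deterministic across simulated raw reads
  sm <- small_sim(seed = 71, n_reads = 400L, k = 1L)
  bcm <- base_composition(sm$sim$reads)
  linker <- strsplit("CAGCAG", "")[[1L]]
  for (i in seq_along(linker)) {
    expect_equal(unname(bcm[4L + i, linker[i]]), nrow(sm$sim$reads))
  }
})

test_that("survival accounting chains stages and computes retention", {
  st <- survival_table(data.frame(stage = "all", reads_in = 100L,
                                  reads_out = 100L))
  expect_equal(st$retention, 1.0)

  st2 <- survival_table(data.frame(stage = c("a", "b"),
                                   reads_in = c(100L, 90L),
                                   reads_out = c(90L, 81L)))
  expect_equal(st2$cumulative[2L], 0.81)

  expect_error(survival_table(data.frame(stage = c("a", "b"),
                                         reads_in = c(100L, 80L),
                                         reads_out = c(90L, 70L))),
               "chaining")
  expect_error(survival_table(data.frame(stage = "a", reads_in = 10L,
                                         reads_out = 12L)), "more reads")
  f <- tempfile(fileext = ".png")
  plot_survival(st2, f)
  expect_true(file.size(f) > 0)
})

test_that("top sequences rank by count with lexicographic ties", {
  expect_equal(top_sequences(reads_of(c("A", "A", "C")), 1L),
               data.frame(sequence = "A", count = 2L,
                          stringsAsFactors = FALSE))
  allx <- top_sequences(reads_of(c("T", "G", "C")), 3L)
  expect_equal(allx$sequence, c("C", "G", "T"))
  expect_equal(allx$count, rep(1L, 3L))
  # an artifact planted at 5% among diverse reads surfaces in the top 3
  set.seed(72)
  diverse <- vapply(1:950, function(i) {
    paste(sample(c("A", "C", "G", "T"), 25L, replace = TRUE), collapse = "")
  }, "")
  artifact <- strrep("CAGCA", 5L)
  top <- top_sequences(reads_of(c(diverse, rep(artifact, 50L))), 3L)
  expect_true(artifact %in% top$sequence)
})

test_that("QC verdict applies both thresholds strictly", {
  expect_true(qc_verdict(0.05, 0.90)$pass)
  v1 <- qc_verdict(0.10, 0.90)
  expect_false(v1$pass)
  expect_match(v1$reasons, "rRNA")
  v2 <- qc_verdict(0.05, 0.70)
  expect_false(v2$pass)
  expect_match(v2$reasons, "mapping")
  expect_error(qc_verdict(1.5, 0.5), "0, 1")
})

test_that("worsening a metric never flips a failing verdict to pass", {
  set.seed(73)
  for (i in 1:50) {
    r1 <- runif(1); m1 <- runif(1)
    r2 <- min(1, r1 + runif(1, 0, 1 - r1))   # worse rRNA
    m2 <- max(0, m1 - runif(1, 0, m1))       # worse mapping
    if (!qc_verdict(r1, m1)$pass) {
      expect_false(qc_verdict(r2, m2)$pass)
    }
  }
})

test_that("pearson correlation flags constant columns and honors transforms", {
  set.seed(74)
  base <- matrix(rexp(60, 0.1), ncol = 3,
                 dimnames = list(NULL, c("a", "b", "c")))
  dup <- cbind(base, d = base[, "a"])
  r <- pearson_matrix(dup)
  expect_equal(unname(r["a", "d"]), 1)
  expect_true(all(diag(r) == 1))
  expect_true(all(r >= -1 & r <= 1))

  neg <- cbind(x = base[, 1L], y = -(base[, 1L] - mean(base[, 1L])))
  expect_equal(unname(pearson_matrix(neg, log_transform = FALSE)["x", "y"]),
               -1)

  const <- base; const[, 2L] <- 5
  expect_error(pearson_matrix(const), "b")
})

test_that("two-group expression yields higher within-group correlation", {
  set.seed(75)
  shift <- rep(c(0, 4), each = 50L)
  expr <- vapply(1:6, function(s) {
    mu <- if (s <= 3) shift else rev(shift)
    exp(mu + rnorm(100L, sd = 0.3))
  }, numeric(100L))
  colnames(expr) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  r <- pearson_matrix(expr)
  within <- c(r["a1", "a2"], r["a1", "a3"], r["a2", "a3"],
              r["b1", "b2"], r["b1", "b3"], r["b2", "b3"])
  between <- as.vector(r[1:3, 4:6])
  expect_gt(min(within), max(between))

  hc <- hcluster(r)
  expect_equal(unname(cutree(hc, 2)), rep(c(1L, 2L), each = 3L))
})

test_that("dendrograms join closest samples first and ignore input order", {
  r <- matrix(c(1, 1, 0.2,
                1, 1, 0.2,
                0.2, 0.2, 1), nrow = 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  hc <- hcluster(r)
  expect_equal(sort(hc$labels[-hc$merge[1L, ]]), c("x", "y"))
  expect_equal(hc$height[1L], 0)          # identical pair joins at 1 - r = 0

  two <- matrix(c(1, 0.4, 0.4, 1), nrow = 2,
                dimnames = list(c("p", "q"), c("p", "q")))
  expect_equal(hcluster(two)$height, 0.6)

  # input order changes only labels, not the partition (co-membership)
  perm <- c(3L, 1L, 2L)
  hc2 <- hcluster(r[perm, perm])
  cut1 <- cutree(hc, 2)[c("x", "y", "z")]
  cut2 <- cutree(hc2, 2)[c("x", "y", "z")]
  expect_equal(outer(cut1, cut1, `==`), outer(cut2, cut2, `==`))
})

test_that("bootstrap probabilities are reproducible and in range", {
  set.seed(76)
  shift <- rep(c(0, 3), each = 40L)
  expr <- vapply(1:6, function(s) {
    mu <- if (s <= 3) shift else rev(shift)
    exp(mu + rnorm(80L, sd = 0.4))
  }, numeric(80L))
  colnames(expr) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  bp <- bootstrap_bp(expr, n_boot = 30L, seed = 4L)
  expect_true(all(bp$bp >= 0 & bp$bp <= 1))
  expect_identical(bp, bootstrap_bp(expr, n_boot = 30L, seed = 4L))
  true_nodes <- c("a1|a2|a3", "b1|b2|b3")
  expect_true(all(bp$bp[bp$node %in% true_nodes] >= 0.9))
  f <- tempfile(fileext = ".png")
  plot_correlation_heatmap(pearson_matrix(expr), f)
  expect_true(file.size(f) > 0)
})
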