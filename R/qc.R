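#' Per-position base composition of a read set
#'
#' @param reads Read table.
#' @return Integer matrix, positions x `c("A","C","G","T","N")`; column
#'   `p` sums to the number of reads at least `p` bases long.
#' @export
base_composition <- function(reads) {
  bases <- c("A", "C", "G", "T", "N")
  if (!nrow(reads)) {
    return(matrix(0L, nrow = 0L, ncol = 5L, dimnames = list(NULL, bases)))
  }
  maxlen <- max(nchar(reads$sequence))
  out <- matrix(0L, nrow = maxlen, ncol = 5L, dimnames = list(NULL, bases))
  for (p in seq_len(maxlen)) {
    ch <- substr(reads$sequence, p, p)
    ch <- ch[nzchar(ch)]
    tb <- table(factor(ch, levels = bases))
    out[p, ] <- as.integer(tb)
  }
  out
}

#' Read-survival accounting across pipeline stages
#'
#' @param stages Data frame with columns `stage`, `reads_in`,
#'   `reads_out`; consecutive stages must chain (`reads_in` of stage k
#'   equals `reads_out` of stage k-1) and no stage may emit more reads
#'   than it received.
#' @return The table with `retention` (per stage) and `cumulative`
#'   retention columns added, of class `survival_table`.
#' @export
survival_table <- function(stages) {
  stopifnot(all(c("stage", "reads_in", "reads_out") %in% names(stages)))
  if (any(stages$reads_out > stages$reads_in)) {
    stop("a stage cannot emit more reads than it received")
  }
  n <- nrow(stages)
  if (n > 1L && any(stages$reads_in[-1L] != stages$reads_out[-n])) {
    stop("inconsistent chaining: reads_in must equal previous reads_out")
  }
  stages$retention <- ifelse(stages$reads_in > 0,
                             stages$reads_out / stages$reads_in, 0)
  stages$cumulative <- if (stages$reads_in[1L] > 0) {
    stages$reads_out / stages$reads_in[1L]
  } else {
    rep(0, n)
  }
  class(stages) <- c("survival_table", "data.frame")
  stages
}

#' Render a survival table as a bar plot (PNG)
#'
#' @param table A [survival_table()].
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
plot_survival <- function(table, path) {
  png(path, width = 640, height = 480)
  on.exit(dev.off())
  par(mar = c(8, 4, 2, 1))
  barplot(table$reads_out, names.arg = table$stage, las = 2,
          ylab = "reads passing", col = "steelblue",
          main = "Read survival per stage")
  invisible(path)
}

#' Most frequent sequences in a read set
#'
#' Useful for spotting linker concatemers and other artifacts that
#' dominate a library.
#'
#' @param reads Read table.
#' @param n Number of entries to return (>= 1).
#' @return Data frame `sequence`, `count`, descending by count with ties
#'   broken lexicographically.
#' @export
top_sequences <- function(reads, n) {
  if (n < 1L) stop("n must be >= 1")
  tab <- table(reads$sequence)
  df <- data.frame(sequence = names(tab), count = as.integer(tab),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$count, df$sequence), , drop = FALSE]
  rownames(df) <- NULL
  utils::head(df, n)
}

#' QC thresholds for CAGE library acceptance
#'
#' A library is of acceptable quality when fewer than 10 percent of its
#' reads are ribosomal RNA and its mapping rate exceeds 70 percent; both
#' bounds are strict and configurable.
#'
#' @param max_rrna_fraction rRNA fraction must be strictly below this
#'   (default 0.10).
#' @param min_mapping_rate Mapping rate must be strictly above this
#'   (default 0.70).
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(max_rrna_fraction = 0.10, min_mapping_rate = 0.70) {
  if (max_rrna_fraction <= 0 || max_rrna_fraction >= 1 ||
      min_mapping_rate <= 0 || min_mapping_rate >= 1) {
    stop("thresholds must be in (0, 1)")
  }
  structure(list(max_rrna_fraction = max_rrna_fraction,
                 min_mapping_rate = min_mapping_rate),
            class = "qc_thresholds")
}

#' Library quality verdict
#'
#' @param rrna_fraction Fraction of reads matching rRNA, in `[0, 1]`.
#' @param mapping_rate Fraction of filtered reads that mapped, in
#'   `[0, 1]`.
#' @param thresholds A [qc_thresholds()] object.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   violated rules, empty on pass).
#' @export
qc_verdict <- function(rrna_fraction, mapping_rate,
                       thresholds = qc_thresholds()) {
  if (rrna_fraction < 0 || rrna_fraction > 1 ||
      mapping_rate < 0 || mapping_rate > 1) {
    stop("rrna_fraction and mapping_rate must be in [0, 1]")
  }
  reasons <- character(0)
  if (!(rrna_fraction < thresholds$max_rrna_fraction)) {
    reasons <- c(reasons, sprintf(
      "rRNA fraction %.3f is not below %.3f", rrna_fraction,
      thresholds$max_rrna_fraction))
  }
  if (!(mapping_rate > thresholds$min_mapping_rate)) {
    reasons <- c(reasons, sprintf(
      "mapping rate %.3f is not above %.3f", mapping_rate,
      thresholds$min_mapping_rate))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

#' Pearson correlation between samples on peak expression
#'
#' By default expression values are `log(x + 1)`-transformed before
#' correlating, so the result is not dominated by the few strongest
#' peaks; set `log_transform = FALSE` for raw-scale correlation.
#'
#' @param expr Numeric matrix, peaks x samples (e.g. CPM-normalized
#'   [tome_query()] output).
#' @param log_transform Apply `log(x + 1)` first (default TRUE).
#' @return Symmetric sample x sample correlation matrix with unit
#'   diagonal.
#' @export
pearson_matrix <- function(expr, log_transform = TRUE) {
  if (ncol(expr) < 2L || nrow(expr) < 2L) {
    stop("need at least 2 samples and 2 peaks")
  }
  x <- if (log_transform) log1p(expr) else expr
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression column for sample(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  }
  r <- stats::cor(x, method = "pearson")
  diag(r) <- 1
  r
}

#' Hierarchical clustering of samples from a correlation matrix
#'
#' Agglomerative clustering on distance `1 - r` with average linkage.
#'
#' @param corr Correlation matrix from [pearson_matrix()].
#' @return An [stats::hclust] object.
#' @export
hcluster <- function(corr) {
  hclust(as.dist(1 - corr), method = "average")
}

# the sample-name set of every internal node of an hclust tree,
# serialized as a sorted "|"-joined key
dendrogram_node_sets <- function(hc) {
  labs <- hc$labels
  merge <- hc$merge
  sets <- vector("list", nrow(merge))
  for (k in seq_len(nrow(merge))) {
    members <- unlist(lapply(merge[k, ], function(m) {
      if (m < 0) labs[-m] else sets[[m]]
    }))
    sets[[k]] <- sort(members)
  }
  vapply(sets, paste, "", collapse = "|")
}

#' Bootstrap probabilities for dendrogram nodes
#'
#' Resamples peaks (rows) with replacement `n_boot` times, reclusters
#' the samples each time, and reports for every internal node of the
#' original dendrogram the fraction of replicates in which the same
#' sample set reappears as a node (the bootstrap probability, BP).
#' Replicates whose resampled expression leaves a sample constant are
#' correlated with that sample's correlations set to 0.
#'
#' @param expr Peaks x samples expression matrix.
#' @param n_boot Number of bootstrap replicates (>= 1; default 100).
#' @param seed RNG seed for reproducibility.
#' @param log_transform Passed to the internal correlation (default
#'   TRUE).
#' @return Data frame `node` (sorted `|`-joined member names), `bp` in
#'   `[0, 1]`, one row per internal node of the original tree, plus the
#'   original [stats::hclust] object as attribute `hclust`.
#' @export
bootstrap_bp <- function(expr, n_boot = 100L, seed = 1L,
                         log_transform = TRUE) {
  if (n_boot < 1L) stop("n_boot must be >= 1")
  boot_cor <- function(m) {
    x <- if (log_transform) log1p(m) else m
    r <- suppressWarnings(stats::cor(x, method = "pearson"))
    r[is.na(r)] <- 0
    diag(r) <- 1
    r
  }
  hc <- hcluster(boot_cor(expr))
  orig <- dendrogram_node_sets(hc)
  hits <- setNames(numeric(length(orig)), orig)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(expr), nrow(expr), replace = TRUE)
    bhc <- hcluster(boot_cor(expr[rows, , drop = FALSE]))
    bsets <- dendrogram_node_sets(bhc)
    found <- orig %in% bsets
    hits[found] <- hits[found] + 1
  }
  out <- data.frame(node = orig, bp = as.numeric(hits) / n_boot,
                    stringsAsFactors = FALSE)
  attr(out, "hclust") <- hc
  out
}

#' Write a correlation heatmap PNG
#'
#' Fixed blue-white-red color scale over `[-1, 1]`; the numbers behind
#' the figure should be written alongside with [write.table()] so the
#' plot itself carries no unique information.
#'
#' @param corr Correlation matrix.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
plot_correlation_heatmap <- function(corr, path) {
  png(path, width = 640, height = 640)
  on.exit(dev.off())
  pal <- grDevices::colorRampPalette(c("blue", "white", "red"))(101)
  n <- ncol(corr)
  graphics::image(seq_len(n), seq_len(n), t(corr[n:1, , drop = FALSE]),
                  zlim = c(-1, 1), col = pal, axes = FALSE,
                  xlab = "", ylab = "", main = "Sample correlation")
  graphics::axis(1, at = seq_len(n), labels = colnames(corr), las = 2)
  graphics::axis(2, at = seq_len(n), labels = rev(rownames(corr)), las = 2)
  invisible(path)
}
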