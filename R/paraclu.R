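# Sentinel density/stability used where the true value is infinite:
# single-site clusters have no proper prefix/suffix (max_density = +Inf)
# and the root cluster has min_density 0 (stability = +Inf).  Both are
# capped at this documented constant so downstream tables stay numeric.
DENSITY_SENTINEL <- 1e9

cap_sentinel <- function(x) pmin(x, DENSITY_SENTINEL)

#' Parametric density clustering of CTSS (Paraclu)
#'
#' Clusters the tag counts of one chromosome strand into the full nested
#' hierarchy of density clusters.  For a density parameter `d`, a cluster
#' is a maximal scoring segment for score = total count − d × span;
#' varying `d` yields nested intervals, each maximal over a density range
#' (`min_density`, `max_density`).  The recursion finds, for the current
#' site range, the prefix or suffix removal of minimum density
#' (count per base of genomic span); that density is the enclosing
#' cluster's `max_density` and the corresponding breakpoint splits the
#' range into two children which inherit it as their `min_density`.  Ties
#' in the minimum break density are resolved at the leftmost breakpoint.
#' `stability = max_density / min_density` measures how robust a cluster
#' is; infinite values (single-site clusters, the root) are capped at a
#' sentinel constant of `1e9`.
#'
#' @param ctss CTSS data frame restricted to a single chromosome and
#'   strand, sorted by position.
#' @param min_density Density at which the root cluster merges with its
#'   surroundings (default 0, i.e. report the full hierarchy).
#' @return Data frame of clusters: `chrom`, `strand`, `start`, `end`
#'   (0-based half-open over covered positions), `total_count`,
#'   `n_sites`, `min_density`, `max_density`, `stability`; only clusters
#'   with `max_density > min_density` are reported; children follow
#'   parents.
#' @references Frith et al. (2008) "A code for transcription initiation
#'   in mammalian genomes", Genome Research 18:1-12 (the Paraclu
#'   algorithm).
#' @export
paraclu <- function(ctss, min_density = 0) {
  validate_ctss(ctss)
  if (!nrow(ctss)) {
    return(empty_clusters())
  }
  if (length(unique(ctss$chrom)) != 1L || length(unique(ctss$strand)) != 1L) {
    stop("paraclu input must be a single chromosome and strand")
  }
  if (is.unsorted(ctss$pos, strictly = TRUE)) {
    stop("paraclu input must be sorted by position")
  }
  pos <- as.numeric(ctss$pos)
  cnt <- as.numeric(ctss$count)
  S <- c(0, cumsum(cnt))             # S[k+1] = sum of counts 1..k
  res_start <- integer(0); res_end <- integer(0)
  res_min <- numeric(0); res_max <- numeric(0)
  res_total <- numeric(0); res_n <- integer(0)
  # explicit stack: ranges are site-index ranges [i, j]
  stack <- list(list(i = 1L, j = length(pos), min_d = min_density))
  while (length(stack)) {
    fr <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- fr$i; j <- fr$j; min_d <- fr$min_d
    if (i == j) {
      max_d <- DENSITY_SENTINEL
      brk <- NA_integer_
    } else {
      k <- (i + 1L):j
      pref <- (S[k] - S[i]) / (pos[k] - pos[i])          # remove sites i..k-1
      suf <- (S[j + 1L] - S[k]) / (pos[j] - pos[k - 1L]) # remove sites k..j
      dens <- pmin(pref, suf)
      max_d <- min(dens)
      brk <- k[which.max(dens == max_d)]                 # leftmost tie-break
    }
    if (max_d > min_d) {
      res_start <- c(res_start, ctss$pos[i])
      res_end <- c(res_end, ctss$pos[j] + 1L)
      res_min <- c(res_min, min_d); res_max <- c(res_max, max_d)
      res_total <- c(res_total, S[j + 1L] - S[i])
      res_n <- c(res_n, j - i + 1L)
    }
    if (i < j) {
      child_min <- max(min_d, max_d)
      # push right child first so the left child is processed first
      stack[[length(stack) + 1L]] <- list(i = brk, j = j, min_d = child_min)
      stack[[length(stack) + 1L]] <- list(i = i, j = brk - 1L, min_d = child_min)
    }
  }
  data.frame(chrom = ctss$chrom[1L], strand = ctss$strand[1L],
             start = res_start, end = res_end, total_count = res_total,
             n_sites = res_n, min_density = res_min,
             max_density = cap_sentinel(res_max),
             stability = stability_of(res_min, res_max),
             stringsAsFactors = FALSE)
}

stability_of <- function(min_d, max_d) {
  out <- ifelse(min_d <= 0, DENSITY_SENTINEL, max_d / min_d)
  cap_sentinel(out)
}

empty_clusters <- function() {
  data.frame(chrom = character(), strand = character(), start = integer(),
             end = integer(), total_count = numeric(), n_sites = integer(),
             min_density = numeric(), max_density = numeric(),
             stability = numeric(), stringsAsFactors = FALSE)
}

#' Run Paraclu over all chromosomes and strands of a CTSS table
#'
#' @param ctss CTSS data frame (any chromosomes/strands; need not be
#'   sorted).
#' @param min_density Passed to [paraclu()].
#' @return Combined cluster data frame.
#' @export
paraclu_all <- function(ctss, min_density = 0) {
  validate_ctss(ctss)
  if (!nrow(ctss)) return(empty_clusters())
  ctss <- ctss[order(ctss$chrom, match(ctss$strand, c("+", "-")),
                     ctss$pos), , drop = FALSE]
  key <- paste(ctss$chrom, ctss$strand)
  parts <- split(ctss, factor(key, levels = unique(key)))
  out <- do.call(rbind, lapply(parts, paraclu, min_density = min_density))
  rownames(out) <- NULL
  out
}

#' Select CAGE peaks from a Paraclu cluster hierarchy
#'
#' Keeps clusters of genomic length at most `max_length` bases and
#' stability strictly greater than `min_stability` (defaults 200 bp and
#' 2), then reduces nested survivors to the outermost qualifying
#' clusters so the returned peaks are non-overlapping.
#'
#' @param clusters Cluster data frame from [paraclu()]/[paraclu_all()].
#' @param max_length Maximum peak length in bases (default 200).
#' @param min_stability Stability must exceed this value (strictly;
#'   default 2).
#' @param min_count Optional minimum total tag count (default 0 = off).
#' @return Data frame of selected, non-nested peaks sorted by
#'   (chrom, strand, start).
#' @export
select_peaks <- function(clusters, max_length = 200L, min_stability = 2,
                         min_count = 0) {
  ok <- (clusters$end - clusters$start) <= max_length &
    clusters$stability > min_stability &
    clusters$total_count >= min_count
  surv <- clusters[ok, , drop = FALSE]
  if (!nrow(surv)) {
    out <- surv
    rownames(out) <- NULL
    return(out)
  }
  surv <- surv[order(surv$chrom, surv$strand, surv$start, -surv$end), ,
               drop = FALSE]
  keep <- logical(nrow(surv))
  cur_chrom <- ""; cur_strand <- ""; cur_end <- -1
  for (r in seq_len(nrow(surv))) {
    new_group <- surv$chrom[r] != cur_chrom || surv$strand[r] != cur_strand
    if (new_group || surv$start[r] >= cur_end) {
      keep[r] <- TRUE
      cur_chrom <- surv$chrom[r]; cur_strand <- surv$strand[r]
      cur_end <- surv$end[r]
    }
    # else: clusters are laminar, so this one is nested in the kept one
  }
  out <- surv[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write peaks as BED6+ (extra density columns)
#'
#' Columns: chrom, start, end, name, total_count, strand, min_density,
#' max_density, stability.
#'
#' @param peaks Cluster data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_peaks_bed <- function(peaks, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%.6g\t%.6g\t%.6g",
                   peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end),
                   sprintf("peak_%d", seq_len(nrow(peaks))),
                   format(peaks$total_count, trim = TRUE),
                   peaks$strand, peaks$min_density, peaks$max_density,
                   peaks$stability)
  writeLines(lines, path)
  invisible(path)
}
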