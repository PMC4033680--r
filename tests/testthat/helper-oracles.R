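# Independent oracles used to verify the density clustering and the CSR
# store.  They share no code with the implementations they check.

oracle_sentinel <- 1e9

# Ruzzo & Tompa (1999): all maximal scoring subsequences of a score
# vector, by the published list algorithm.
rt_maximal_segments <- function(score) {
  st <- integer(0); en <- integer(0); L <- numeric(0); R <- numeric(0)
  cum <- 0
  for (i in seq_along(score)) {
    x <- score[i]
    if (x > 0) {
      cs <- i; ce <- i; cl <- cum; cr <- cum + x
      repeat {
        k <- length(L); j <- 0L
        while (k >= 1L) {
          if (L[k] < cl) { j <- k; break }
          k <- k - 1L
        }
        if (j == 0L || R[j] >= cr) {
          st <- c(st, cs); en <- c(en, ce); L <- c(L, cl); R <- c(R, cr)
          break
        }
        cs <- st[j]; cl <- L[j]
        keep <- seq_len(j - 1L)
        st <- st[keep]; en <- en[keep]; L <- L[keep]; R <- R[keep]
      }
    }
    cum <- cum + x
  }
  cbind(st, en)
}

# maximal scoring segments of a site profile at fixed density d,
# as site-index ranges (score = counts - d * span)
segments_at_density <- function(pos, cnt, d) {
  n <- length(pos)
  elem_score <- numeric(2L * n - 1L)
  elem_site <- integer(2L * n - 1L)
  odd <- seq(1L, 2L * n - 1L, by = 2L)
  elem_score[odd] <- cnt - d
  elem_site[odd] <- seq_len(n)
  if (n > 1L) {
    elem_score[seq(2L, 2L * n - 2L, by = 2L)] <- -(pos[-1L] - pos[-n] - 1L) * d
  }
  seg <- rt_maximal_segments(elem_score)
  if (!nrow(seg)) return(NULL)
  cbind(elem_site[seg[, 1L]], elem_site[seg[, 2L]])
}

# brute-force cluster enumeration: sweep the density parameter across
# all critical values, collect every maximal scoring segment, and read
# off each segment's density range from the critical grid.  Single-site
# clusters get the sentinel max density (shared convention).
paraclu_bruteforce <- function(pos, cnt) {
  n <- length(pos)
  S <- c(0, cumsum(cnt))
  D <- c()
  for (a in seq_len(n)) {
    if (a < n) {
      b <- (a + 1L):n
      D <- c(D, (S[b] - S[a]) / (pos[b] - pos[a]))         # prefix removals
      D <- c(D, (S[b + 1L] - S[a + 1L]) / (pos[b] - pos[a])) # suffix removals
    }
    b2 <- a:n
    D <- c(D, (S[b2 + 1L] - S[a]) / (pos[b2] - pos[a] + 1L)) # segment densities
  }
  D <- sort(unique(c(0, D, cnt)))
  mids <- (D[-length(D)] + D[-1L]) / 2
  seen <- new.env(parent = emptyenv())
  for (t in seq_along(mids)) {
    segs <- segments_at_density(pos, cnt, mids[t])
    if (is.null(segs)) next
    for (r in seq_len(nrow(segs))) {
      key <- paste(segs[r, 1L], segs[r, 2L])
      e <- get0(key, envir = seen)
      if (is.null(e)) assign(key, c(t, t), envir = seen)
      else assign(key, c(min(e[1L], t), max(e[2L], t)), envir = seen)
    }
  }
  out <- lapply(ls(seen), function(key) {
    ij <- as.integer(strsplit(key, " ")[[1L]])
    tt <- get(key, envir = seen)
    i <- ij[1L]; j <- ij[2L]
    maxd <- if (i == j) oracle_sentinel else D[tt[2L] + 1L]
    c(pos[i], pos[j] + 1L, D[tt[1L]], maxd, S[j + 1L] - S[i], j - i + 1L)
  })
  m <- do.call(rbind, out)
  m[order(m[, 1L], -m[, 2L]), , drop = FALSE]
}

# check one random instance: every brute-force cluster must appear in the
# recursion output with matching densities; recursion clusters absent
# from the sweep must be single sites already merged below their own
# density (min_density >= count), which the sentinel convention reports
# regardless.
expect_paraclu_matches_bruteforce <- function(ctss) {
  cl <- paraclu(ctss)
  cl <- cl[order(cl$start, -cl$end), , drop = FALSE]
  got <- cbind(cl$start, cl$end, cl$min_density, cl$max_density,
               cl$total_count, cl$n_sites)
  hidden <- got[, 6L] == 1L & got[, 3L] >= got[, 5L]
  orc <- paraclu_bruteforce(ctss$pos, ctss$count)
  expect_equal(unname(got[!hidden, , drop = FALSE]), unname(orc),
               tolerance = 1e-9)
}

# per-position brute-force interval sum over raw CTSS libraries
brute_interval_counts <- function(libraries, interval) {
  vapply(libraries, function(lib) {
    sel <- lib$chrom == interval$chrom &
      lib$pos >= interval$start & lib$pos < interval$end
    if (interval$strand != ".") sel <- sel & lib$strand == interval$strand
    sum(lib$count[sel])
  }, 0)
}
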