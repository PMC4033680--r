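#' Build a Tome store from per-sample CTSS tables
#'
#' The Tome store holds mapped CAGE counts from multiple experiments in a
#' compressed sparse row layout: per (chromosome, strand), a strictly
#' increasing position array with row pointers into parallel arrays of
#' sample column indices and counts.  It is write-once, read-many and is
#' queried with BED6 intervals (see [tome_query()]).
#'
#' @param libraries Named list mapping sample name to a CTSS data frame.
#' @return A `tome_store` object.
#' @export
build_store <- function(libraries) {
  if (!length(libraries)) stop("at least one library is required")
  samples <- names(libraries)
  if (is.null(samples) || any(!nzchar(samples))) {
    stop("libraries must be a named list")
  }
  if (anyDuplicated(samples)) stop("duplicate sample name")
  for (lib in libraries) validate_ctss(lib)
  all <- do.call(rbind, lapply(seq_along(libraries), function(s) {
    lib <- libraries[[s]]
    if (!nrow(lib)) return(NULL)
    data.frame(chrom = lib$chrom, strand = lib$strand, pos = lib$pos,
               s = s, count = lib$count, stringsAsFactors = FALSE)
  }))
  blocks <- list()
  if (!is.null(all) && nrow(all)) {
    all <- all[order(all$chrom, match(all$strand, c("+", "-")), all$pos,
                     all$s), , drop = FALSE]
    bkey <- paste0(all$chrom, "\r", all$strand)
    for (part in split(all, factor(bkey, levels = unique(bkey)))) {
      upos <- unique(part$pos)
      row_id <- match(part$pos, upos)
      row_ptr <- c(0L, cumsum(tabulate(row_id, nbins = length(upos))))
      key <- paste0(part$chrom[1L], "|", part$strand[1L])
      blocks[[key]] <- list(chrom = part$chrom[1L], strand = part$strand[1L],
                            pos = as.integer(upos),
                            row_ptr = as.integer(row_ptr),
                            col = as.integer(part$s),
                            val = as.integer(part$count))
    }
  }
  sizes <- vapply(libraries, function(lib) sum(as.numeric(lib$count)), 0)
  structure(list(samples = samples,
                 library_sizes = setNames(as.numeric(sizes), samples),
                 blocks = blocks),
            class = "tome_store")
}

#' @export
print.tome_store <- function(x, ...) {
  cat("tome_store:", length(x$samples), "samples,",
      length(x$blocks), "chrom/strand blocks,",
      sum(vapply(x$blocks, function(b) length(b$val), 0L)),
      "stored cells\n")
  invisible(x)
}

block_query <- function(block, start, end, n_samples) {
  out <- numeric(n_samples)
  if (is.null(block)) return(out)
  pos <- block$pos
  i_lo <- findInterval(start - 0.5, pos) + 1L   # first pos >= start
  i_hi <- findInterval(end - 0.5, pos)          # last pos < end
  if (i_hi >= i_lo) {
    sel <- (block$row_ptr[i_lo] + 1L):block$row_ptr[i_hi + 1L]
    cols <- block$col[sel]
    vals <- block$val[sel]
    for (u in seq_along(cols)) out[cols[u]] <- out[cols[u]] + vals[u]
  }
  out
}

#' Query a Tome store with BED6 intervals
#'
#' Returns, per interval and sample, the total tag count at stored
#' positions `p` with `start <= p < end` on the interval's chromosome.
#' Stranded intervals (`+`/`-`) restrict to the matching strand;
#' unstranded (`.`) intervals sum both strands.  Lookup is by binary
#' search over the position array.
#'
#' @param store A [build_store()] result.
#' @param intervals BED6 data frame (see [parse_bed6()]).
#' @return Numeric matrix, intervals x samples; row names are
#'   `chrom:start-end,strand`.  Intervals on chromosomes absent from the
#'   store yield zero rows; such chromosomes are recorded in the
#'   `unknown_chroms` attribute.
#' @export
tome_query <- function(store, intervals) {
  stopifnot(inherits(store, "tome_store"))
  ns <- length(store$samples)
  mat <- matrix(0, nrow = nrow(intervals), ncol = ns,
                dimnames = list(sprintf("%s:%d-%d,%s", intervals$chrom,
                                        intervals$start, intervals$end,
                                        intervals$strand),
                                store$samples))
  known <- unique(vapply(store$blocks, function(b) b$chrom, ""))
  unknown <- character(0)
  for (r in seq_len(nrow(intervals))) {
    chrom <- intervals$chrom[r]
    if (!(chrom %in% known)) {
      unknown <- union(unknown, chrom)
      next
    }
    strands <- if (intervals$strand[r] == ".") c("+", "-") else intervals$strand[r]
    for (s in strands) {
      mat[r, ] <- mat[r, ] + block_query(store$blocks[[paste0(chrom, "|", s)]],
                                         intervals$start[r], intervals$end[r],
                                         ns)
    }
  }
  attr(mat, "unknown_chroms") <- unknown
  mat
}

#' Counts-per-million normalization
#'
#' @param mat Raw count matrix (intervals x samples), columns in the
#'   order of `library_sizes`.
#' @param library_sizes Positive per-sample total counts.
#' @return Matrix of `raw * 1e6 / library_size`.
#' @export
normalize_cpm <- function(mat, library_sizes) {
  if (length(library_sizes) != ncol(mat)) {
    stop("library_sizes must match the number of samples")
  }
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  sweep(mat, 2L, library_sizes, function(x, s) x * 1e6 / s)
}

#' Fraction of each library's tags falling in promoter intervals
#'
#' Overlapping promoter intervals are merged (per chromosome and strand)
#' before summation so no tag is double-counted.  This per-library
#' promoter fraction is a CAGE quality indicator.
#'
#' @param store A [build_store()] result.
#' @param promoters BED6 data frame of promoter intervals.
#' @return Named numeric vector of fractions in `[0, 1]` per sample.
#' @export
promoter_fraction <- function(store, promoters) {
  stopifnot(inherits(store, "tome_store"))
  if (!nrow(promoters)) {
    return(setNames(numeric(length(store$samples)), store$samples))
  }
  gr <- GRanges(promoters$chrom,
                IRanges(promoters$start + 1L, promoters$end),
                strand = sub("^\\.$", "*", promoters$strand))
  gr <- reduce(gr)
  merged <- data.frame(chrom = as.character(seqnames(gr)),
                       start = start(gr) - 1L, end = end(gr),
                       name = ".", score = 0,
                       strand = sub("^\\*$", ".", as.character(strand(gr))),
                       stringsAsFactors = FALSE)
  counts <- colSums(tome_query(store, merged))
  setNames(as.numeric(counts / store$library_sizes), store$samples)
}

#' Save a Tome store to a single file
#'
#' The format is a one-line JSON header (samples, library sizes, block
#' table) followed, per block, by four lines of space-separated integers
#' (positions, row pointers, sample column indices, counts).  Reloading
#' with [load_tome()] reproduces the store bit-identically.
#'
#' @param store A `tome_store`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
save_tome <- function(store, path) {
  stopifnot(inherits(store, "tome_store"))
  header <- toJSON(list(
    magic = "tome", version = 1L, samples = store$samples,
    library_sizes = as.numeric(store$library_sizes),
    blocks = lapply(store$blocks, function(b) {
      list(chrom = b$chrom, strand = b$strand, n_pos = length(b$pos),
           nnz = length(b$val))
    })), auto_unbox = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  for (b in store$blocks) {
    writeLines(paste(b$pos, collapse = " "), con)
    writeLines(paste(b$row_ptr, collapse = " "), con)
    writeLines(paste(b$col, collapse = " "), con)
    writeLines(paste(b$val, collapse = " "), con)
  }
  invisible(path)
}

#' Load a Tome store saved by [save_tome()]
#'
#' @param path File path.
#' @return A `tome_store`.
#' @export
load_tome <- function(path) {
  lines <- readLines(path)
  header <- fromJSON(lines[1L], simplifyVector = FALSE)
  if (!identical(header$magic, "tome")) stop("not a tome file")
  samples <- as.character(unlist(header$samples))
  blocks <- list()
  at <- 2L
  ints <- function(s) as.integer(strsplit(s, " ", fixed = TRUE)[[1L]])
  for (hb in header$blocks) {
    key <- paste0(hb$chrom, "|", hb$strand)
    blocks[[key]] <- list(chrom = hb$chrom, strand = hb$strand,
                          pos = ints(lines[at]),
                          row_ptr = ints(lines[at + 1L]),
                          col = ints(lines[at + 2L]),
                          val = ints(lines[at + 3L]))
    at <- at + 4L
  }
  structure(list(samples = samples,
                 library_sizes = setNames(as.numeric(unlist(header$library_sizes)),
                                          samples),
                 blocks = blocks),
            class = "tome_store")
}
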