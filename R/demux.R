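#' Barcode specifications for demultiplexing
#'
#' CAGE libraries are pooled into one lane with a per-sample barcode
#' followed by a fixed linker (`CAGCAG` by default) at the read 5' end.
#' This constructor validates that barcodes are unambiguous: all the same
#' length and pairwise Hamming distance greater than `2 * max_mismatch`,
#' so no read prefix can match two barcodes.
#'
#' @param samples Character vector of sample names.
#' @param barcodes Character vector of barcodes over `A,C,G,T`, one per
#'   sample, all the same length.
#' @param linker Linker sequence expected right after the barcode
#'   (default `"CAGCAG"`).
#' @param max_mismatch Maximum mismatches tolerated in the barcode and in
#'   the linker match (default 0; the conservative default avoids
#'   cross-sample bleed).
#' @return A `barcode_specs` object (data frame of sample/barcode with
#'   linker and max_mismatch attributes).
#' @export
barcode_specs <- function(samples, barcodes, linker = "CAGCAG",
                          max_mismatch = 0L) {
  if (length(samples) == 0L) stop("at least one barcode spec is required")
  if (length(samples) != length(barcodes)) {
    stop("samples and barcodes must have equal length")
  }
  if (anyDuplicated(samples)) stop("duplicate sample name")
  if (length(unique(nchar(barcodes))) != 1L) {
    stop("all barcodes must have equal length")
  }
  if (any(grepl("[^ACGT]", barcodes))) stop("barcodes must be over A,C,G,T")
  if (max_mismatch < 0L) stop("max_mismatch must be >= 0")
  bmat <- do.call(rbind, strsplit(barcodes, ""))
  for (i in seq_along(barcodes)) {
    for (j in seq_len(i - 1L)) {
      if (sum(bmat[i, ] != bmat[j, ]) <= 2L * max_mismatch) {
        stop("barcodes ", barcodes[i], " and ", barcodes[j],
             " are within Hamming distance ", 2L * max_mismatch)
      }
    }
  }
  specs <- data.frame(sample = samples, barcode = barcodes,
                      stringsAsFactors = FALSE)
  attr(specs, "linker") <- linker
  attr(specs, "max_mismatch") <- as.integer(max_mismatch)
  class(specs) <- c("barcode_specs", "data.frame")
  specs
}

#' Read a barcode table (TSV: sample<TAB>barcode)
#'
#' @param path Path to a two-column tab-separated file.
#' @param ... Passed to [barcode_specs()] (`linker`, `max_mismatch`).
#' @return A `barcode_specs` object.
#' @export
read_barcodes <- function(path, ...) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("sample", "barcode"),
                   colClasses = "character")
  barcode_specs(df$sample, df$barcode, ...)
}

hamming_to <- function(seqs, pattern) {
  # mismatches between each fixed-length string in seqs and pattern;
  # strings shorter than pattern count as no match (Inf)
  n <- nchar(pattern)
  out <- rep(Inf, length(seqs))
  ok <- nchar(seqs) >= n
  if (any(ok)) {
    pm <- strsplit(pattern, "")[[1L]]
    sm <- do.call(rbind, strsplit(substr(seqs[ok], 1L, n), ""))
    out[ok] <- rowSums(sm != matrix(pm, nrow = sum(ok), ncol = n, byrow = TRUE))
  }
  out
}

#' Demultiplex pooled CAGE reads by barcode
#'
#' Each read is expected to start with `[barcode][linker][tag]`.  A read
#' is assigned to the unique sample whose barcode matches the read prefix
#' within `max_mismatch` mismatches and whose linker matches the
#' following bases within the same tolerance; assigned reads are returned
#' with barcode and linker trimmed off (sequence and quality).  Reads
#' failing either match go to the `"unassigned"` bin untrimmed.  For
#' paired-end input the assignment is decided by read 1 and the mate
#' travels with it unmodified.
#'
#' @param reads Read table (see [parse_fastq()]).
#' @param specs A [barcode_specs()] object.
#' @param reads2 Optional mate read table, matched to `reads` by row.
#' @return A named list with one read table per sample plus
#'   `"unassigned"`.  With `reads2`, each element is a list with `R1` and
#'   `R2` tables.
#' @export
split_by_barcode <- function(reads, specs, reads2 = NULL) {
  if (!inherits(specs, "barcode_specs")) stop("specs must be barcode_specs")
  if (!is.null(reads2) && nrow(reads2) != nrow(reads)) {
    stop("reads and reads2 must have the same number of records")
  }
  linker <- attr(specs, "linker")
  mm <- attr(specs, "max_mismatch")
  blen <- nchar(specs$barcode[1L])
  llen <- nchar(linker)

  assign <- rep(NA_integer_, nrow(reads))
  if (nrow(reads)) {
    dists <- vapply(specs$barcode, function(b) hamming_to(reads$sequence, b),
                    numeric(nrow(reads)))
    dists <- matrix(dists, nrow = nrow(reads))
    hits <- dists <= mm
    nhit <- rowSums(hits)
    # spec invariant guarantees at most one hit; guard anyway
    one <- nhit == 1L
    assign[one] <- max.col(hits[one, , drop = FALSE], ties.method = "first")
    # linker must follow the barcode within the same mismatch budget
    tail_ok <- hamming_to(substr(reads$sequence, blen + 1L, nchar(reads$sequence)),
                          linker) <= mm
    assign[!tail_ok] <- NA_integer_
  }

  out <- vector("list", nrow(specs) + 1L)
  names(out) <- c(specs$sample, "unassigned")
  for (k in seq_len(nrow(specs))) {
    sel <- which(!is.na(assign) & assign == k)
    r1 <- reads[sel, , drop = FALSE]
    r1$sequence <- substr(r1$sequence, blen + llen + 1L, nchar(r1$sequence))
    r1$quality <- substr(r1$quality, blen + llen + 1L, nchar(r1$quality))
    rownames(r1) <- NULL
    out[[k]] <- if (is.null(reads2)) r1 else {
      r2 <- reads2[sel, , drop = FALSE]; rownames(r2) <- NULL
      list(R1 = r1, R2 = r2)
    }
  }
  sel <- which(is.na(assign))
  un <- reads[sel, , drop = FALSE]
  rownames(un) <- NULL
  out[["unassigned"]] <- if (is.null(reads2)) un else {
    r2 <- reads2[sel, , drop = FALSE]; rownames(r2) <- NULL
    list(R1 = un, R2 = r2)
  }
  out
}

#' Remove reads containing ambiguous bases
#'
#' Drops every read whose sequence contains an `N`; input order is
#' preserved among the kept reads.
#'
#' @param reads Read table.
#' @return List with `kept` (read table) and `removed_count`.
#' @export
remove_ambiguous <- function(reads) {
  keep <- !grepl("N", reads$sequence, fixed = TRUE)
  kept <- reads[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed_count = sum(!keep))
}
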