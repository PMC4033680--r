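#' Extract CAGE transcription start sites from alignments
#'
#' The 5' end of each mapped read is a single genomic base: for a
#' plus-strand alignment the leftmost aligned base (`start`), for a
#' minus-strand alignment the rightmost (`end - 1`).  Identical
#' (chrom, pos, strand) sites are aggregated and their read counts
#' summed, so the sum of CTSS counts equals the number of mapped
#' alignments supplied.
#'
#' @param alignments Data frame as returned by [read_alignments()]
#'   (columns `chrom`, `start`, `end`, `strand`, `mapped`).
#' @return CTSS data frame (`chrom`, `pos`, `strand`, `count`) sorted by
#'   (chrom, strand, pos).  The number of unmapped records skipped is
#'   attached as attribute `n_unmapped`.
#' @examples
#' aln <- data.frame(read_id = c("a", "b"), chrom = "chr1",
#'                   start = c(100L, 100L), end = c(120L, 120L),
#'                   strand = c("+", "-"), mapped = TRUE)
#' extract_ctss(aln)
#' @export
extract_ctss <- function(alignments) {
  stopifnot(all(c("chrom", "start", "end", "strand", "mapped") %in%
                  names(alignments)))
  n_unmapped <- sum(!alignments$mapped)
  aln <- alignments[alignments$mapped, , drop = FALSE]
  if (nrow(aln)) {
    if (any(aln$start >= aln$end)) stop("mapped alignment with start >= end")
    if (!all(aln$strand %in% c("+", "-"))) stop("alignment strand must be + or -")
  }
  pos <- ifelse(aln$strand == "+", aln$start, aln$end - 1L)
  key <- paste(aln$chrom, aln$strand, pos, sep = "\r")
  tab <- table(key)
  if (length(tab)) {
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    ctss <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                       pos = as.integer(vapply(parts, `[`, "", 3L)),
                       strand = vapply(parts, `[`, "", 2L),
                       count = as.integer(tab), stringsAsFactors = FALSE)
    ctss <- ctss[order(ctss$chrom, match(ctss$strand, c("+", "-")),
                       ctss$pos), , drop = FALSE]
    rownames(ctss) <- NULL
  } else {
    ctss <- data.frame(chrom = character(), pos = integer(),
                       strand = character(), count = integer(),
                       stringsAsFactors = FALSE)
  }
  attr(ctss, "n_unmapped") <- n_unmapped
  ctss
}
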