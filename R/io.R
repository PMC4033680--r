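#' Parse a FASTQ file into a read table
#'
#' Reads 4-line-per-record FASTQ into a data frame of read records.  All
#' coordinates and conventions in cagekit are BED-native: sequences are
#' plain upper-case character strings over `A,C,G,T,N`.
#'
#' @param path Path to an uncompressed FASTQ file.
#' @return A data frame with columns `id`, `sequence`, `quality`
#'   (one row per read, in file order).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' parse_fastq(fq)
#' @export
parse_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n == 0L) {
    return(data.frame(id = character(), sequence = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (n %% 4L != 0L) {
    stop("malformed FASTQ: ", n, " lines is not a multiple of 4 (near line ", n, ")")
  }
  idx <- seq(1L, n, by = 4L)
  hdr <- lines[idx]
  seqs <- lines[idx + 1L]
  plus <- lines[idx + 2L]
  qual <- lines[idx + 3L]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ record: missing '@' at line ", idx[bad[1L]])
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad)) {
    stop("malformed FASTQ record: missing '+' at line ", idx[bad[1L]] + 2L)
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ record: sequence/quality length mismatch at line ",
         idx[bad[1L]] + 1L)
  }
  data.frame(id = sub("^@", "", hdr), sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Write a read table as FASTQ
#'
#' @param reads Data frame with columns `id`, `sequence`, `quality`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality") %in% names(reads)))
  if (any(nchar(reads$sequence) != nchar(reads$quality))) {
    stop("sequence/quality length mismatch")
  }
  out <- character(4L * nrow(reads))
  if (nrow(reads)) {
    out[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$id)
    out[c(FALSE, TRUE, FALSE, FALSE)] <- reads$sequence
    out[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
    out[c(FALSE, FALSE, FALSE, TRUE)] <- reads$quality
  }
  writeLines(out, path)
  invisible(path)
}

#' Parse a BED6 file of genomic intervals
#'
#' Coordinates are 0-based half-open, as in the BED standard; the strand
#' column may be `+`, `-` or `.` (unstranded).
#'
#' @param path Path to a tab-delimited BED file with at least 6 columns.
#' @return Data frame with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
parse_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      name = character(), score = numeric(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 6L)) {
    stop("BED6 requires >= 6 columns; line ", which(ncol < 6L)[1L], " has ",
         ncol[which(ncol < 6L)[1L]])
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("non-integer coordinates at line ", which(is.na(start) | is.na(end))[1L])
  }
  bad <- which(start >= end | start < 0L)
  if (length(bad)) {
    stop("invalid interval (need 0 <= start < end) at line ", bad[1L])
  }
  strand <- vapply(fields, `[`, "", 6L)
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand column must be one of +, -, .")
  }
  data.frame(chrom = vapply(fields, `[`, "", 1L),
             start = start, end = end,
             name = vapply(fields, `[`, "", 4L),
             score = suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L))),
             strand = strand, stringsAsFactors = FALSE)
}

#' Write genomic intervals as BED6
#'
#' @param intervals Data frame as returned by [parse_bed6()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bed6 <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end", "name", "score", "strand") %in%
                  names(intervals)))
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   intervals$chrom, as.integer(intervals$start),
                   as.integer(intervals$end), intervals$name,
                   format(intervals$score, trim = TRUE, scientific = FALSE),
                   intervals$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()].
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector of DNA sequences.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a CTSS table
#'
#' The CTSS text format is `chrom<TAB>pos<TAB>strand<TAB>count`, one line
#' per site, with `pos` a 0-based single-base position.
#'
#' @param path CTSS file path.
#' @return Data frame with columns `chrom`, `pos`, `strand`, `count`.
#' @export
read_ctss <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "pos", "strand", "count"),
                   colClasses = c("character", "integer", "character", "integer"))
  validate_ctss(df)
  df
}

#' Write a CTSS table
#'
#' @param ctss Data frame with columns `chrom`, `pos`, `strand`, `count`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_ctss <- function(ctss, path) {
  validate_ctss(ctss)
  writeLines(sprintf("%s\t%d\t%s\t%d", ctss$chrom, as.integer(ctss$pos),
                     ctss$strand, as.integer(ctss$count)), path)
  invisible(path)
}

validate_ctss <- function(ctss) {
  stopifnot(all(c("chrom", "pos", "strand", "count") %in% names(ctss)))
  if (nrow(ctss)) {
    if (!all(ctss$strand %in% c("+", "-"))) stop("CTSS strand must be + or -")
    if (any(ctss$count < 1L)) stop("CTSS counts must be >= 1")
    if (anyDuplicated(paste(ctss$chrom, ctss$pos, ctss$strand))) {
      stop("duplicate (chrom, pos, strand) in CTSS table")
    }
  }
  invisible(TRUE)
}

#' Read gene models from BED12
#'
#' BED12 blocks become exons; `thickStart`/`thickEnd` are interpreted as
#' the CDS span.  A model with `thickStart == thickEnd` is treated as
#' non-coding.
#'
#' @param path BED12 file path.
#' @return A gene-model data frame with columns `chrom`, `tx_start`,
#'   `tx_end`, `name`, `score`, `strand`, `cds_start`, `cds_end` and
#'   list-columns `exon_starts`, `exon_ends` (absolute 0-based half-open
#'   coordinates).
#' @export
read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12L)) {
    stop("BED12 requires 12 columns; line ",
         which(lengths(fields) < 12L)[1L], " has fewer")
  }
  f <- function(i) vapply(fields, `[`, "", i)
  models <- data.frame(chrom = f(1L), tx_start = as.integer(f(2L)),
                       tx_end = as.integer(f(3L)), name = f(4L),
                       score = as.numeric(f(5L)), strand = f(6L),
                       cds_start = as.integer(f(7L)), cds_end = as.integer(f(8L)),
                       stringsAsFactors = FALSE)
  n_blocks <- as.integer(f(10L))
  sizes <- strsplit(sub(",$", "", f(11L)), ",", fixed = TRUE)
  starts <- strsplit(sub(",$", "", f(12L)), ",", fixed = TRUE)
  models$exon_starts <- lapply(seq_along(fields), function(i) {
    models$tx_start[i] + as.integer(starts[[i]])
  })
  models$exon_ends <- lapply(seq_along(fields), function(i) {
    models$exon_starts[[i]] + as.integer(sizes[[i]])
  })
  if (any(lengths(models$exon_starts) != n_blocks)) {
    stop("blockCount does not match blockStarts")
  }
  validate_gene_models(models)
  models
}

#' Write gene models as BED12
#'
#' @param models Gene-model data frame as returned by [read_bed12()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_bed12 <- function(models, path) {
  validate_gene_models(models)
  lines <- vapply(seq_len(nrow(models)), function(i) {
    es <- models$exon_starts[[i]]
    ee <- models$exon_ends[[i]]
    sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%d\t%d\t0\t%d\t%s\t%s",
            models$chrom[i], models$tx_start[i], models$tx_end[i],
            models$name[i], format(models$score[i], trim = TRUE),
            models$strand[i], models$cds_start[i], models$cds_end[i],
            length(es),
            paste0(paste(ee - es, collapse = ","), ","),
            paste0(paste(es - models$tx_start[i], collapse = ","), ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

validate_gene_models <- function(models) {
  for (i in seq_len(nrow(models))) {
    es <- models$exon_starts[[i]]
    ee <- models$exon_ends[[i]]
    if (is.unsorted(es, strictly = TRUE) || any(ee <= es) ||
        any(es[-1L] < ee[-length(ee)])) {
      stop("exons must be sorted and non-overlapping (gene ", models$name[i], ")")
    }
    if (es[1L] != models$tx_start[i] || ee[length(ee)] != models$tx_end[i]) {
      stop("first/last exon must touch transcript bounds (gene ", models$name[i], ")")
    }
    with(models[i, ], {
      if (!(tx_start <= cds_start && cds_start <= cds_end && cds_end <= tx_end)) {
        stop("need tx_start <= cds_start <= cds_end <= tx_end (gene ", name, ")")
      }
    })
  }
  invisible(TRUE)
}

#' Read mapped reads as alignment records
#'
#' Thin adapter turning SAM, BAM or BED6 input into the alignment-record
#' table consumed by [extract_ctss()].  Only chromosome, aligned span,
#' strand and the mapped flag are kept; for SAM/BAM the aligned span is
#' the reference span of the CIGAR, so soft-clipped bases are excluded.
#' Coordinates in the result are 0-based half-open.
#'
#' @param path Path to a `.sam`, `.bam` or `.bed` file.
#' @return Data frame with columns `read_id`, `chrom`, `start`, `end`,
#'   `strand`, `mapped`.  Unmapped SAM/BAM records appear with
#'   `mapped = FALSE` and `NA` coordinates.
#' @export
read_alignments <- function(path) {
  ext <- tolower(file_ext(path))
  if (ext == "bed") {
    bed <- parse_bed6(path)
    if (!all(bed$strand %in% c("+", "-"))) {
      stop("alignment BED input must be stranded")
    }
    return(data.frame(read_id = bed$name, chrom = bed$chrom, start = bed$start,
                      end = bed$end, strand = bed$strand, mapped = TRUE,
                      stringsAsFactors = FALSE))
  }
  bam <- path
  if (ext == "sam") {
    bam <- asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  } else if (ext != "bam") {
    stop("unsupported alignment format: ", ext)
  }
  ga <- readGAlignments(bam, use.names = TRUE)
  mapped <- data.frame(read_id = names(ga),
                       chrom = as.character(GenomeInfoDb::seqnames(ga)),
                       start = BiocGenerics::start(ga) - 1L,
                       end = BiocGenerics::end(ga),
                       strand = as.character(BiocGenerics::strand(ga)),
                       mapped = TRUE, stringsAsFactors = FALSE)
  n_unmapped <- countBam(bam, param = ScanBamParam(
    flag = scanBamFlag(isUnmappedQuery = TRUE)))$records
  if (n_unmapped > 0L) {
    un <- data.frame(read_id = sprintf("unmapped_%d", seq_len(n_unmapped)),
                     chrom = NA_character_, start = NA_integer_,
                     end = NA_integer_, strand = NA_character_,
                     mapped = FALSE, stringsAsFactors = FALSE)
    mapped <- rbind(mapped, un)
  }
  mapped
}

revcomp <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}
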