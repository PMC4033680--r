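# Category names in priority order; "intergenic" is the implicit terminal
# category for tags falling in none of them.
annotation_categories <- c("upstream", "utr5", "cds", "utr3",
                           "intron", "downstream")

gr0 <- function(chrom, start0, end0, strand) {
  keep <- end0 > start0
  GRanges(chrom[keep], IRanges(start0[keep] + 1L, end0[keep]),
          strand = strand[keep])
}

#' Build the hierarchical annotation of a set of gene models
#'
#' Derives, per gene and in fixed priority order, the six annotation
#' categories used to classify CAGE tags: `upstream` (`flank` bases 5' of
#' the transcript start, strand-aware), `utr5` (exonic bases between the
#' transcript start and the CDS on the coding strand), `cds` (exonic
#' bases within the CDS), `utr3`, `intron` (transcript span minus exons)
#' and `downstream` (`flank` bases 3' of the transcript end).  Intervals
#' are clipped at position 0 and merged within each category.  Tags
#' overlapping none of the categories are later classed `intergenic`.
#' Non-coding models (`cds_start == cds_end`) contribute all exonic bases
#' to the `utr5` slot (a single generic "exon" class).
#'
#' @param models Gene-model data frame (see [read_bed12()]).
#' @param flank Flank size in bases for upstream/downstream (default 100).
#' @return An `annotation_hierarchy`: named list of [GenomicRanges::GRanges]
#'   in priority order, with a `flank` attribute.
#' @export
build_hierarchy <- function(models, flank = 100L) {
  if (flank <= 0L) stop("flank must be > 0")
  validate_gene_models(models)
  acc <- setNames(vector("list", length(annotation_categories)),
                  annotation_categories)
  for (cat in annotation_categories) acc[[cat]] <- list()
  for (i in seq_len(nrow(models))) {
    chrom <- models$chrom[i]; strand <- models$strand[i]
    txs <- models$tx_start[i]; txe <- models$tx_end[i]
    cs <- models$cds_start[i]; ce <- models$cds_end[i]
    exons <- IRanges(models$exon_starts[[i]] + 1L, models$exon_ends[[i]])
    tx <- IRanges(txs + 1L, txe)
    plus <- strand == "+"
    up0 <- if (plus) c(max(0L, txs - flank), txs) else c(txe, txe + flank)
    dn0 <- if (plus) c(txe, txe + flank) else c(max(0L, txs - flank), txs)
    add <- function(cat, ir) {
      if (length(ir) && sum(width(ir)) > 0L) {
        acc[[cat]][[length(acc[[cat]]) + 1L]] <<-
          GRanges(chrom, ir, strand = strand)
      }
    }
    add("upstream", IRanges(up0[1L] + 1L, up0[2L]))
    add("downstream", IRanges(dn0[1L] + 1L, dn0[2L]))
    if (cs == ce) {
      # non-coding: all exonic bases in the utr5 ("exon") slot
      add("utr5", exons)
    } else {
      cds_ir <- IRanges(cs + 1L, ce)
      left_ir <- if (txs < cs) IRanges(txs + 1L, cs) else IRanges()
      right_ir <- if (ce < txe) IRanges(ce + 1L, txe) else IRanges()
      add("cds", intersect(exons, cds_ir))
      add(if (plus) "utr5" else "utr3", intersect(exons, left_ir))
      add(if (plus) "utr3" else "utr5", intersect(exons, right_ir))
    }
    add("intron", setdiff(tx, exons))
  }
  hier <- lapply(acc, function(lst) {
    if (length(lst)) suppressWarnings(reduce(do.call(c, lst))) else GRanges()
  })
  structure(hier, flank = as.integer(flank), class = "annotation_hierarchy")
}

#' Export an annotation hierarchy as per-category BED6 files
#'
#' @param hierarchy An [build_hierarchy()] result.
#' @param dir Output directory; one `<category>.bed` file per category.
#' @return Invisibly, the written file paths.
#' @export
write_hierarchy_bed <- function(hierarchy, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(hierarchy), function(cat) {
    gr <- hierarchy[[cat]]
    df <- data.frame(chrom = as.character(seqnames(gr)),
                     start = start(gr) - 1L, end = end(gr),
                     name = cat, score = 0,
                     strand = as.character(strand(gr)),
                     stringsAsFactors = FALSE)
    write_bed6(df, file.path(dir, paste0(cat, ".bed")))
  }, "")
  invisible(paths)
}

#' Annotate CTSS against a category hierarchy
#'
#' Each CTSS position is assigned to the first (highest-priority)
#' category whose intervals contain it; its full tag count accrues
#' there, so every tag is annotated to exactly one category.  Positions
#' contained in no category accrue to `intergenic`.  By default the
#' intersection ignores strand (plain interval overlap); set
#' `stranded = TRUE` to require matching strands.
#'
#' @param ctss CTSS data frame.
#' @param hierarchy An [build_hierarchy()] result.
#' @param stranded Require strand match (default FALSE).
#' @return Named numeric vector of tag counts per category (categories in
#'   priority order plus `intergenic`); sums to `sum(ctss$count)`.
#' @export
annotate_ctss <- function(ctss, hierarchy, stranded = FALSE) {
  counts <- setNames(numeric(length(hierarchy) + 1L),
                     c(names(hierarchy), "intergenic"))
  if (!nrow(ctss)) return(counts)
  validate_ctss(ctss)
  gr <- GRanges(ctss$chrom, IRanges(ctss$pos + 1L, width = 1L),
                strand = ctss$strand)
  remaining <- rep(TRUE, length(gr))
  for (cat in names(hierarchy)) {
    if (!any(remaining) || length(hierarchy[[cat]]) == 0L) next
    hit <- overlapsAny(gr[remaining], hierarchy[[cat]],
                       ignore.strand = !stranded)
    idx <- which(remaining)[hit]
    counts[[cat]] <- sum(ctss$count[idx])
    remaining[idx] <- FALSE
  }
  counts[["intergenic"]] <- sum(ctss$count[remaining])
  counts
}

#' Summarize per-library category counts as a fraction table
#'
#' @param per_library Named list mapping library name to a named count
#'   vector as returned by [annotate_ctss()].
#' @return Data frame with one row per library: `library`, `total`,
#'   raw `count.<category>` columns and `frac.<category>` columns
#'   (fractions sum to 1 per row; a zero-tag library yields an all-zero
#'   row with `note == "zero_tags"`).
#' @export
annotation_table <- function(per_library) {
  if (!length(per_library)) stop("at least one library is required")
  cats <- names(per_library[[1L]])
  rows <- lapply(names(per_library), function(lib) {
    cnt <- per_library[[lib]][cats]
    total <- sum(cnt)
    frac <- if (total > 0) cnt / total else cnt * 0
    df <- data.frame(library = lib, total = total, stringsAsFactors = FALSE)
    for (ct in cats) df[[paste0("count.", ct)]] <- unname(cnt[[ct]])
    for (ct in cats) df[[paste0("frac.", ct)]] <- unname(frac[[ct]])
    df$note <- if (total > 0) "" else "zero_tags"
    df
  })
  do.call(rbind, rows)
}

#' Write an annotation table as TSV
#'
#' @param table Result of [annotation_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
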