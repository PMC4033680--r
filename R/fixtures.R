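#' Generate a deterministic toy genome
#'
#' Uniform random A/C/G/T sequence per chromosome; the same seed always
#' yields the same genome (R's Mersenne-Twister integer-state RNG).
#'
#' @param seed RNG seed.
#' @param chrom_sizes Named integer vector of chromosome sizes (>= 1 kb
#'   each).
#' @return Named character vector of sequences.
#' @export
make_toy_genome <- function(seed = 1L,
                            chrom_sizes = c(chr1 = 100000L, chr2 = 60000L)) {
  if (any(chrom_sizes < 1000L)) stop("chromosome sizes must be >= 1 kb")
  set.seed(seed)
  vapply(chrom_sizes, function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, "")
}

# map an offset into the concatenated exonic sequence (0-based) back to a
# genomic coordinate
exonic_to_genomic <- function(es, ee, off) {
  w <- ee - es
  cw <- cumsum(w)
  i <- which(off < cw)[1L]
  prev <- if (i == 1L) 0L else cw[i - 1L]
  es[i] + (off - prev)
}

#' Generate non-overlapping synthetic gene models
#'
#' Genes are laid out sequentially with gaps large enough that 100 bp
#' flanks never overlap a neighbour; strands, exon counts (1-4) and CDS
#' bounds are randomized.  About 15 percent of models are non-coding
#' (`cds_start == cds_end`).
#'
#' @param genome Named character vector from [make_toy_genome()].
#' @param n_genes Number of genes.
#' @param seed RNG seed.
#' @return Gene-model data frame (see [read_bed12()]).
#' @export
make_gene_models <- function(genome, n_genes = 20L, seed = 1L) {
  set.seed(seed)
  sizes <- nchar(genome)
  chroms <- names(genome)
  alloc <- pmax(1L, round(n_genes * sizes / sum(sizes)))
  while (sum(alloc) > n_genes) alloc[which.max(alloc)] <- alloc[which.max(alloc)] - 1L
  while (sum(alloc) < n_genes) alloc[which.max(sizes)] <- alloc[which.max(sizes)] + 1L
  rows <- list()
  g <- 0L
  for (ci in seq_along(chroms)) {
    cursor <- 200L
    for (k in seq_len(alloc[ci])) {
      tx_len <- sample(600:1500, 1L)
      if (cursor + tx_len + 250L > sizes[ci]) {
        stop("chromosome ", chroms[ci], " too small for requested gene count")
      }
      g <- g + 1L
      txs <- cursor
      txe <- txs + tx_len
      n_ex <- sample(1:4, 1L)
      if (n_ex == 1L) {
        es <- txs; ee <- txe
      } else {
        pieces <- 2L * n_ex - 1L
        w <- rep(60L, pieces)
        extra <- tx_len - sum(w)
        w <- w + as.integer(stats::rmultinom(1L, extra, rep(1, pieces)))
        bounds <- txs + c(0L, cumsum(w))
        es <- bounds[seq(1L, pieces, by = 2L)]
        ee <- bounds[seq(2L, pieces + 1L, by = 2L)]
      }
      E <- sum(ee - es)
      if (stats::runif(1L) < 0.15) {
        cs <- ce <- txs
      } else {
        a <- as.integer(floor(0.2 * E)); b <- as.integer(floor(0.85 * E))
        cs <- exonic_to_genomic(es, ee, a)
        ce <- exonic_to_genomic(es, ee, b - 1L) + 1L
      }
      rows[[g]] <- data.frame(
        chrom = chroms[ci], tx_start = txs, tx_end = txe,
        name = sprintf("gene_%d", g), score = 0,
        strand = sample(c("+", "-"), 1L),
        cds_start = cs, cds_end = ce, stringsAsFactors = FALSE)
      rows[[g]]$exon_starts <- list(as.integer(es))
      rows[[g]]$exon_ends <- list(as.integer(ee))
      cursor <- txe + sample(220:400, 1L)
    }
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL
  validate_gene_models(models)
  models
}

intersect_intervals <- function(starts, ends, lo, hi) {
  s <- pmax(starts, lo); e <- pmin(ends, hi)
  keep <- e > s
  cbind(s[keep], e[keep])
}

# per-gene category intervals (0-based half-open), computed with plain
# integer arithmetic, independently of build_hierarchy()
gene_category_intervals <- function(model, flank = 100L) {
  es <- model$exon_starts[[1L]]; ee <- model$exon_ends[[1L]]
  txs <- model$tx_start; txe <- model$tx_end
  cs <- model$cds_start; ce <- model$cds_end
  plus <- model$strand == "+"
  out <- list()
  out$upstream <- if (plus) cbind(max(0L, txs - flank), txs) else
    cbind(txe, txe + flank)
  out$downstream <- if (plus) cbind(txe, txe + flank) else
    cbind(max(0L, txs - flank), txs)
  if (cs == ce) {
    out$utr5 <- cbind(es, ee)
    out$cds <- out$utr3 <- matrix(0L, 0L, 2L)
  } else {
    out$cds <- intersect_intervals(es, ee, cs, ce)
    left <- intersect_intervals(es, ee, txs, cs)
    right <- intersect_intervals(es, ee, ce, txe)
    out$utr5 <- if (plus) left else right
    out$utr3 <- if (plus) right else left
  }
  if (length(es) > 1L) {
    out$intron <- cbind(ee[-length(ee)], es[-1L])
  } else {
    out$intron <- matrix(0L, 0L, 2L)
  }
  out
}

# complement of gene spans +/- margin over the genome, clipped at chrom
# ends with a safety margin for tag extraction
intergenic_intervals <- function(genome, models, margin = 150L) {
  out <- list()
  for (chrom in names(genome)) {
    size <- nchar(genome[[chrom]])
    m <- models[models$chrom == chrom, , drop = FALSE]
    occ_s <- m$tx_start - margin; occ_e <- m$tx_end + margin
    free_s <- c(40L, occ_e); free_e <- c(occ_s, size - 40L)
    keep <- free_e > free_s
    if (any(keep)) {
      out[[chrom]] <- cbind(free_s[keep], free_e[keep])
    }
  }
  out
}

pick_position <- function(iv, n) {
  # n uniform positions over a 2-column interval matrix, weighted by width
  w <- iv[, 2L] - iv[, 1L]
  i <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  iv[i, 1L] + floor(stats::runif(n) * w[i])
}

decay_offsets <- function(n, width) {
  # small offsets 0..width-1 with geometrically decaying probability,
  # emulating a sharp promoter with minor positional dispersion
  p <- 0.55 ^ (seq_len(width) - 1L)
  sample.int(width, n, replace = TRUE, prob = p) - 1L
}

#' Simulate a multiplexed CAGE sequencing run with truth table
#'
#' Emits reads laid out as `[barcode][CAGCAG linker][tag]`.  Tags are
#' genome substrings drawn from a category mix anchored at the gene
#' models (promoter-proximal categories cluster tightly around the
#' annotated TSS so that density clustering has real peaks to find);
#' planted rRNA and artifact reads are allocated deterministically by
#' rounded per-sample quotas so truth fractions are exact.  With
#' `n_rate > 0`, reads independently receive one ambiguous base (`N`) in
#' the tag with that probability and are marked class `ambiguous`.  With
#' `group_effect > 1`, samples are split into two groups, each
#' preferring one half of the genes by that expression fold change.
#'
#' @param genome [make_toy_genome()] result.
#' @param models [make_gene_models()] result.
#' @param barcodes Named character vector, sample name -> barcode.
#' @param n_reads Total reads across all samples (default 10000).
#' @param rrna_fraction Fraction of planted rRNA reads (default 0.05).
#' @param artifact_fraction Fraction of planted artifact reads
#'   (default 0.02).
#' @param n_rate Per-read probability of an injected N (default 0).
#' @param error_rate Per-base substitution error probability
#'   (default 0).
#' @param tag_length Tag length in bases (default 25).
#' @param category_mix Named fractions over annotation categories plus
#'   `intergenic` for the genomic class of each tag.
#' @param group_effect Between-group expression fold change (default 1 =
#'   no group structure).
#' @param seed RNG seed.
#' @return List with `reads` (multiplexed read table in shuffled order),
#'   `truth` (one row per read: `id`, `sample`, `class`, `category`,
#'   `chrom`, `pos`, `strand`, `gene`, `group`), `rrna_ref`,
#'   `artifact_seqs`, `barcodes`, `groups`, `tag_length`.
#' @export
simulate_cage_reads <- function(genome, models, barcodes,
                                n_reads = 10000L,
                                rrna_fraction = 0.05,
                                artifact_fraction = 0.02,
                                n_rate = 0, error_rate = 0,
                                tag_length = 25L,
                                category_mix = c(upstream = 0.15,
                                                 utr5 = 0.40, cds = 0.15,
                                                 utr3 = 0.05, intron = 0.10,
                                                 downstream = 0.03,
                                                 intergenic = 0.12),
                                group_effect = 1, seed = 1L) {
  if (rrna_fraction + artifact_fraction > 1) {
    stop("contaminant fractions must sum to <= 1")
  }
  samples <- names(barcodes)
  k <- length(samples)
  linker <- "CAGCAG"
  # contaminant references come from a seed stream distinct from the
  # genome's, so a shared seed cannot make the reference a genome copy
  set.seed(seed + 104729L)
  rrna_ref <- c(rRNA_synthetic = paste(
    sample(c("A", "C", "G", "T"), 1800L, replace = TRUE), collapse = ""))
  artifact_seqs <- c(
    linker_dimer = strrep(linker, 8L),
    adapter_synthetic = paste(sample(c("A", "C", "G", "T"), 40L,
                                     replace = TRUE), collapse = ""))
  set.seed(seed)
  groups <- if (group_effect > 1) {
    setNames(rep(c("A", "B"), c(ceiling(k / 2), floor(k / 2))), samples)
  } else setNames(rep(NA_character_, k), samples)

  n_genes <- nrow(models)
  base_w <- stats::rlnorm(n_genes, meanlog = 0, sdlog = 0.6)
  first_half <- seq_len(n_genes) <= n_genes / 2
  gene_cats <- lapply(seq_len(n_genes), function(i) {
    gene_category_intervals(models[i, , drop = FALSE])
  })
  inter_iv <- intergenic_intervals(genome, models,
                                   margin = 150L + tag_length)

  per_sample <- diff(round(seq(0, n_reads, length.out = k + 1L)))
  rows <- list()
  for (si in seq_len(k)) {
    ns <- per_sample[si]
    n_rrna <- round(ns * rrna_fraction)
    n_art <- round(ns * artifact_fraction)
    n_tag <- ns - n_rrna - n_art
    w <- base_w
    if (group_effect > 1) {
      boost <- if (groups[si] == "A") first_half else !first_half
      w <- w * ifelse(boost, group_effect, 1)
    }
    df <- data.frame(sample = rep(samples[si], ns),
                     class = rep(c("tag", "rRNA", "artifact"),
                                 c(n_tag, n_rrna, n_art)),
                     category = NA_character_, chrom = NA_character_,
                     pos = NA_integer_, strand = NA_character_,
                     gene = NA_character_, tag = NA_character_,
                     stringsAsFactors = FALSE)
    if (n_tag > 0L) {
      gi <- sample.int(n_genes, n_tag, replace = TRUE, prob = w)
      cat_i <- sample(names(category_mix), n_tag, replace = TRUE,
                      prob = category_mix)
      for (r in seq_len(n_tag)) {
        if (cat_i[r] == "intergenic") {
          chrom <- sample(names(inter_iv), 1L)
          pos <- pick_position(inter_iv[[chrom]], 1L)
          strand <- sample(c("+", "-"), 1L)
          df$category[r] <- "intergenic"
          df$chrom[r] <- chrom; df$pos[r] <- pos; df$strand[r] <- strand
          next
        }
        gm <- models[gi[r], , drop = FALSE]
        cats <- gene_cats[[gi[r]]]
        want <- cat_i[r]
        if (nrow(cats[[want]]) == 0L) {
          avail <- names(cats)[vapply(cats, nrow, 0L) > 0L]
          want <- avail[1L]
        }
        plus <- gm$strand == "+"
        if (want %in% c("upstream", "utr5")) {
          # cluster tightly around the annotated TSS
          iv <- cats[[want]]
          if (want == "upstream") {
            width <- min(10L, sum(iv[, 2L] - iv[, 1L]))
            off <- decay_offsets(1L, width)
            pos <- if (plus) gm$tx_start - 1L - off else gm$tx_end + off
          } else {
            lim <- if (plus) min(10L, iv[1L, 2L] - iv[1L, 1L]) else
              min(10L, iv[nrow(iv), 2L] - iv[nrow(iv), 1L])
            off <- decay_offsets(1L, max(1L, lim))
            pos <- if (plus) gm$tx_start + off else gm$tx_end - 1L - off
          }
        } else {
          pos <- pick_position(cats[[want]], 1L)
        }
        df$category[r] <- want
        df$chrom[r] <- gm$chrom; df$pos[r] <- pos
        df$strand[r] <- gm$strand; df$gene[r] <- gm$name
      }
    }
    rows[[si]] <- df
  }
  truth <- do.call(rbind, rows)

  # tag sequences: genomic for class tag, reference substrings otherwise
  truth$tag <- NA_character_
  for (chrom in unique(truth$chrom[!is.na(truth$chrom)])) {
    seqchar <- genome[[chrom]]
    sel <- which(truth$class == "tag" & truth$chrom == chrom)
    p <- truth$pos[sel]; plus <- truth$strand[sel] == "+"
    fw <- substring(seqchar, p + 1L, p + tag_length)
    rv <- substring(seqchar, p - tag_length + 2L, p + 1L)
    tags <- ifelse(plus, fw, rv)
    if (any(!plus)) tags[!plus] <- revcomp(tags[!plus])
    truth$tag[sel] <- tags
  }
  sel <- which(truth$class == "rRNA")
  if (length(sel)) {
    starts <- sample.int(nchar(rrna_ref[[1L]]) - tag_length + 1L,
                         length(sel), replace = TRUE)
    tags <- substring(rrna_ref[[1L]], starts, starts + tag_length - 1L)
    flip <- stats::runif(length(sel)) < 0.5
    if (any(flip)) tags[flip] <- revcomp(tags[flip])
    truth$tag[sel] <- tags
  }
  sel <- which(truth$class == "artifact")
  if (length(sel)) {
    which_art <- sample.int(length(artifact_seqs), length(sel), replace = TRUE)
    truth$tag[sel] <- vapply(which_art, function(a) {
      s <- artifact_seqs[[a]]
      st <- sample.int(nchar(s) - tag_length + 1L, 1L)
      substr(s, st, st + tag_length - 1L)
    }, "")
  }

  # sequencing errors (substitutions) in the tag
  if (error_rate > 0) {
    n_err <- stats::rbinom(nrow(truth), tag_length, error_rate)
    for (r in which(n_err > 0L)) {
      tg <- strsplit(truth$tag[r], "")[[1L]]
      at <- sample.int(tag_length, n_err[r])
      for (a in at) tg[a] <- sample(setdiff(c("A", "C", "G", "T"), tg[a]), 1L)
      truth$tag[r] <- paste(tg, collapse = "")
    }
  }
  # ambiguous-base injection
  if (n_rate > 0) {
    amb <- which(truth$class == "tag" & stats::runif(nrow(truth)) < n_rate)
    for (r in amb) {
      at <- sample.int(tag_length, 1L)
      substr(truth$tag[r], at, at) <- "N"
    }
    truth$class[amb] <- "ambiguous"
  }

  ord <- sample.int(nrow(truth))
  truth <- truth[ord, , drop = FALSE]
  truth$id <- sprintf("read%06d", seq_len(nrow(truth)))
  rownames(truth) <- NULL
  seqs <- paste0(barcodes[truth$sample], linker, truth$tag)
  reads <- data.frame(id = truth$id, sequence = seqs,
                      quality = strrep("I", nchar(seqs)),
                      stringsAsFactors = FALSE)
  truth$group <- unname(groups[truth$sample])
  truth <- truth[, c("id", "sample", "class", "category", "chrom", "pos",
                     "strand", "gene", "group", "tag")]
  list(reads = reads, truth = truth, rrna_ref = rrna_ref,
       artifact_seqs = artifact_seqs, barcodes = barcodes, groups = groups,
       tag_length = tag_length)
}

#' Place simulated reads at their true loci
#'
#' Stands in for an external mapper in tests: every non-contaminant read
#' is mapped exactly at the locus it was drawn from, contaminant reads
#' are unmapped, so the mapping rate equals
#' `1 - rrna_fraction - artifact_fraction` on a clean fixture.
#'
#' @param sim A [simulate_cage_reads()] result.
#' @param read_ids Optional subset of read ids to place (e.g. the reads
#'   surviving demultiplexing and filtering for one sample).
#' @return Alignment data frame (see [read_alignments()]).
#' @export
place_reads <- function(sim, read_ids = NULL) {
  truth <- sim$truth
  if (!is.null(read_ids)) {
    truth <- truth[truth$id %in% read_ids, , drop = FALSE]
  }
  tl <- sim$tag_length
  mapped <- truth$class %in% c("tag", "ambiguous")
  start <- ifelse(truth$strand == "+", truth$pos, truth$pos - tl + 1L)
  end <- ifelse(truth$strand == "+", truth$pos + tl, truth$pos + 1L)
  out <- data.frame(read_id = truth$id, chrom = truth$chrom,
                    start = as.integer(ifelse(mapped, start, NA)),
                    end = as.integer(ifelse(mapped, end, NA)),
                    strand = ifelse(mapped, truth$strand, NA),
                    mapped = mapped, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
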