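#' Read a BED file of genomic intervals
#'
#' BED3+ with optional name/score/strand columns (columns 4-6).  Coordinates
#' are 0-based half-open.  When a genome is supplied, chromosome names and
#' bounds are validated; violations raise an error naming the line.
#'
#' @param path file path.
#' @param genome optional [binned_genome()] for validation.
#' @return data.table with `chrom`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#") &
                  !startsWith(lines, "track"))
  if (!length(keep))
    return(data.table::data.table(chrom = character(), start = numeric(),
                                  end = numeric()))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) parse_error(path, keep[which(nf < 3)[1]], "fewer than 3 BED fields")
  dt <- data.table::data.table(
    chrom = vapply(parts, `[`, "", 1),
    start = suppressWarnings(as.numeric(vapply(parts, `[`, "", 2))),
    end = suppressWarnings(as.numeric(vapply(parts, `[`, "", 3))),
    line = keep)
  if (min(nf) >= 4) dt[, name := vapply(parts, `[`, "", 4)]
  if (min(nf) >= 5) dt[, score := suppressWarnings(as.numeric(vapply(parts, `[`, "", 5)))]
  if (min(nf) >= 6) dt[, strand := vapply(parts, `[`, "", 6)]
  bad <- which(is.na(dt$start) | is.na(dt$end))
  if (length(bad)) parse_error(path, dt$line[bad[1]], "malformed coordinates")
  bad <- which(dt$start < 0 | dt$start >= dt$end)
  if (length(bad)) parse_error(path, dt$line[bad[1]],
                               "interval start must satisfy 0 <= start < end")
  if ("strand" %in% names(dt)) {
    bad <- which(!dt$strand %in% c("+", "-", "."))
    if (length(bad)) parse_error(path, dt$line[bad[1]], "invalid strand")
  }
  if (!is.null(genome)) {
    bad <- which(!dt$chrom %in% genome$chrom)
    if (length(bad)) parse_error(path, dt$line[bad[1]],
                                 paste0("unknown chromosome '", dt$chrom[bad[1]], "'"))
    bad <- which(dt$end > unname(genome$length[dt$chrom]))
    if (length(bad)) parse_error(path, dt$line[bad[1]], "interval beyond chromosome end")
  }
  dt[, line := NULL]
  dt[]
}

#' Write intervals as BED
#' @param intervals data.table with `chrom`, `start`, `end` and optional
#'   `name`, `score`, `strand`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  dt <- data.table::as.data.table(intervals)
  stopifnot(all(c("chrom", "start", "end") %in% names(dt)))
  cols <- c("chrom", "start", "end")
  if ("strand" %in% names(dt)) {
    if (!"name" %in% names(dt)) dt[, name := "."]
    if (!"score" %in% names(dt)) dt[, score := 0]
    cols <- c(cols, "name", "score", "strand")
  } else {
    if ("score" %in% names(dt)) {
      if (!"name" %in% names(dt)) dt[, name := "."]
      cols <- c(cols, "name", "score")
    } else if ("name" %in% names(dt)) cols <- c(cols, "name")
  }
  data.table::fwrite(dt[, cols, with = FALSE], path, sep = "\t",
                     col.names = FALSE)
  invisible(path)
}

#' Read a 5-column gene table
#'
#' Tab-separated `id chrom strand tss tes` (header optional).  TSS/TES are
#' 0-based: a plus-strand gene has `tss < tes`, a minus-strand gene
#' `tss > tes`; the gene body is `[min, max)`.
#'
#' @inheritParams read_bed
#' @return data.table with `id`, `chrom`, `strand`, `tss`, `tes`.
#' @export
read_gene_table <- function(path, genome = NULL) {
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !startsWith(lines, "#"))
  if (length(keep) && identical(strsplit(lines[keep[1]], "\t")[[1]][1], "id"))
    keep <- keep[-1]
  if (!length(keep))
    return(data.table::data.table(id = character(), chrom = character(),
                                  strand = character(), tss = numeric(),
                                  tes = numeric()))
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 5)
  if (length(bad)) parse_error(path, keep[bad[1]], "fewer than 5 gene-table fields")
  dt <- data.table::data.table(
    id = vapply(parts, `[`, "", 1),
    chrom = vapply(parts, `[`, "", 2),
    strand = vapply(parts, `[`, "", 3),
    tss = suppressWarnings(as.numeric(vapply(parts, `[`, "", 4))),
    tes = suppressWarnings(as.numeric(vapply(parts, `[`, "", 5))),
    line = keep)
  bad <- which(is.na(dt$tss) | is.na(dt$tes))
  if (length(bad)) parse_error(path, dt$line[bad[1]], "malformed TSS/TES")
  bad <- which(!dt$strand %in% c("+", "-"))
  if (length(bad)) parse_error(path, dt$line[bad[1]], "gene strand must be + or -")
  bad <- which((dt$strand == "+" & dt$tss >= dt$tes) |
                 (dt$strand == "-" & dt$tss <= dt$tes))
  if (length(bad)) parse_error(path, dt$line[bad[1]],
                               "TSS/TES orientation inconsistent with strand")
  if (!is.null(genome)) {
    bad <- which(!dt$chrom %in% genome$chrom)
    if (length(bad)) parse_error(path, dt$line[bad[1]],
                                 paste0("unknown chromosome '", dt$chrom[bad[1]], "'"))
  }
  dt[, line := NULL]
  dt[]
}

#' Gene body intervals from a gene table
#'
#' `[min(tss, tes), max(tss, tes))` per gene, carrying id and strand.
#'
#' @param genes data.table as returned by [read_gene_table()].
#' @return data.table with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
gene_bodies <- function(genes) {
  g <- data.table::as.data.table(genes)
  data.table::data.table(chrom = g$chrom, start = pmin(g$tss, g$tes),
                         end = pmax(g$tss, g$tes), name = g$id,
                         strand = g$strand)
}

intervals_to_granges <- function(x) {
  dt <- data.table::as.data.table(x)
  strand <- if ("strand" %in% names(dt)) dt$strand else "*"
  GenomicRanges::GRanges(dt$chrom,
                         IRanges::IRanges(start = dt$start + 1, end = dt$end),
                         strand = strand)
}

#' Any-overlap flags between interval sets
#'
#' Half-open arithmetic: intervals sharing only a boundary point do not
#' overlap; >= 1 bp shared does.  With `strand_matched`, only same-strand
#' overlaps count (`.`/missing strand matches everything).
#'
#' @param queries,subjects data.tables with `chrom`, `start`, `end` and
#'   optional `strand`.
#' @param strand_matched enforce same-strand overlap (default FALSE).
#' @return logical vector, one flag per query.
#' @export
overlap_any <- function(queries, subjects, strand_matched = FALSE) {
  q <- data.table::as.data.table(queries)
  s <- data.table::as.data.table(subjects)
  if (nrow(q) == 0) return(logical(0))
  if (nrow(s) == 0) return(rep(FALSE, nrow(q)))
  qg <- intervals_to_granges(q)
  sg <- intervals_to_granges(s)
  IRanges::overlapsAny(qg, sg, minoverlap = 1L, ignore.strand = !strand_matched)
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over reference features (features with all
#' counts positive) of `count / geometric mean across samples`, rescaled so
#' the factors have geometric mean 1.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @return named numeric vector of per-sample factors.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (ncol(counts) == 1) return(stats::setNames(1, colnames(counts)))
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) stop("no feature with all-positive counts")
  logc <- log(counts[ref, , drop = FALSE])
  logmean <- rowMeans(logc)
  sf <- exp(apply(logc - logmean, 2, stats::median))
  sf <- sf / exp(mean(log(sf)))
  stats::setNames(sf, colnames(counts))
}

#' Negative-binomial Wald test for a two-condition count matrix
#'
#' A deliberately simple differential test: counts are normalized by
#' median-of-ratios [size_factors()]; per feature, condition means `m_A`,
#' `m_B` give `log2FC = log2((m_B + pc) / (m_A + pc))`; the NB dispersion
#' is estimated per feature by method-of-moments on normalized counts
#' pooled within condition (floored at 1e-8) and moderated toward the
#' across-feature mean dispersion with `prior_df` pseudo-degrees of
#' freedom; the Wald statistic `z = log2FC / SE` (delta-method SE) yields a
#' two-sided normal p-value and BH q-values.  No shrinkage of fold changes
#' and no outlier filtering is performed.
#'
#' @param counts non-negative integer matrix, features x samples.
#' @param condition_labels character vector (length `ncol(counts)`) with
#'   exactly two levels; the second level in sort order (or factor level
#'   order) is the "B"/numerator condition.
#' @param lfc_threshold minimum `|log2FC|` for the significance flag.
#' @param alpha q-value threshold for the significance flag.
#' @param pc pseudocount for fold-change stabilization (default 0.5).
#' @param prior_df weight (pseudo-df) of the common dispersion in the
#'   moderated per-feature estimate (default 10).
#' @param size_factors optional per-sample normalization factors; `NULL`
#'   (default) estimates them by [size_factors()].  Supply explicit
#'   factors (e.g. all 1) for matrices where median-of-ratios is
#'   undefined, such as sparse CLIP gene counts.
#' @return An object of class `DifferentialResult`: data.table with
#'   `feature`, `base_mean`, `mean_A`, `mean_B`, `log2FC`, `se`, `p_value`,
#'   `q_value`, `significant`; attributes `conditions`, `lfc_threshold`,
#'   `alpha`, `pc`, `size_factors`.
#' @export
nb_test <- function(counts, condition_labels, lfc_threshold = 1, alpha = 0.05,
                    pc = 0.5, prior_df = 10, size_factors = NULL) {
  counts <- as.matrix(counts)
  if (length(condition_labels) != ncol(counts))
    stop("condition_labels must match the number of samples")
  lev <- if (is.factor(condition_labels)) levels(droplevels(condition_labels)) else
    sort(unique(condition_labels))
  if (length(lev) != 2) stop("exactly two conditions required")
  ia <- which(condition_labels == lev[1])
  ib <- which(condition_labels == lev[2])
  if (length(ia) < 2 || length(ib) < 2)
    stop("each condition needs >= 2 replicates")
  sf <- if (is.null(size_factors)) loopscape::size_factors(counts) else {
    stopifnot(length(size_factors) == ncol(counts), all(size_factors > 0))
    size_factors
  }
  norm <- sweep(counts, 2, sf, "/")
  mA <- rowMeans(norm[, ia, drop = FALSE])
  mB <- rowMeans(norm[, ib, drop = FALSE])
  vA <- apply(norm[, ia, drop = FALSE], 1, stats::var)
  vB <- apply(norm[, ib, drop = FALSE], 1, stats::var)
  nA <- length(ia); nB <- length(ib)
  # per-feature MoM dispersion pooled over the two within-condition estimates
  mom <- function(v, m) ifelse(m > 0, (v - m) / m^2, 0)
  disp_i <- pmax(1e-8, ((nA - 1) * mom(vA, mA) + (nB - 1) * mom(vB, mB)) /
                   (nA + nB - 2))
  df_i <- nA + nB - 2
  disp_common <- mean(disp_i)
  disp <- pmax(1e-8, (df_i * disp_i + prior_df * disp_common) /
                 (df_i + prior_df))
  lfc <- log2((mB + pc) / (mA + pc))
  var_mean <- function(m, n) (m + disp * m^2) / n
  se <- sqrt(var_mean(mA, nA) / (mA + pc)^2 + var_mean(mB, nB) / (mB + pc)^2) /
    log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- ifelse(se > 0, 2 * stats::pnorm(-abs(z)), 1)
  q <- bh_adjust(p)
  res <- data.table::data.table(
    feature = if (is.null(rownames(counts))) as.character(seq_len(nrow(counts)))
      else rownames(counts),
    base_mean = rowMeans(norm), mean_A = mA, mean_B = mB,
    log2FC = lfc, se = se, p_value = p, q_value = q,
    significant = q <= alpha & abs(lfc) >= lfc_threshold)
  structure(res, class = c("DifferentialResult", class(res)),
            conditions = lev, lfc_threshold = lfc_threshold, alpha = alpha,
            pc = pc, size_factors = sf)
}

#' Write a differential result as TSV
#' @param result a [nb_test()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(result, path) {
  data.table::fwrite(data.table::as.data.table(result), path, sep = "\t")
  invisible(path)
}
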