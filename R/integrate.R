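#' Two-by-two contingency table with Fisher statistics
#'
#' Builds a `TwoByTwo` from four cell counts (rows = groups, columns =
#' property yes/no), attaching the sample odds ratio `(a d) / (b c)` (with
#' Haldane +0.5 on every cell iff any cell is zero), the conditional-MLE
#' odds ratio from [stats::fisher.test()] as an auxiliary field, and the
#' two-sided Fisher exact p-value from [fisher_exact()].
#'
#' @param a,b,c,d non-negative integer cells: `a`/`b` = group-1
#'   with/without the property, `c`/`d` = group-2 with/without.
#' @param groups,properties optional length-2 dimension labels.
#' @return An object of class `TwoByTwo`: list with `table` (2 x 2
#'   matrix), `odds_ratio`, `odds_ratio_cmle`, `p_value`.
#' @export
two_by_two <- function(a, b, c, d, groups = c("group1", "group2"),
                       properties = c("yes", "no")) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cells must be non-negative integers")
  tab <- matrix(cells, 2, 2, byrow = TRUE,
                dimnames = list(groups, properties))
  fe <- fisher_exact(tab)
  cmle <- unname(stats::fisher.test(tab)$estimate)
  structure(list(table = tab, odds_ratio = fe$odds_ratio,
                 odds_ratio_cmle = cmle, p_value = fe$p_value),
            class = "TwoByTwo")
}

#' @export
print.TwoByTwo <- function(x, ...) {
  print(x$table)
  cat(sprintf("odds ratio %.3f (CMLE %.3f), two-sided Fisher p = %.3g\n",
              x$odds_ratio, x$odds_ratio_cmle, x$p_value))
  invisible(x)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p-value by enumeration: with all margins fixed, the
#' probability of each admissible table is hypergeometric; the p-value is
#' the sum of probabilities of tables no more probable than the observed
#' one (tolerance factor `1 + 1e-7`, as in [stats::fisher.test()]).  The
#' odds ratio is the sample `(a d) / (b c)` with a Haldane +0.5 correction
#' on every cell iff any cell is zero.
#'
#' @param table 2 x 2 non-negative integer matrix (or the four cells
#'   `c(a, b, c, d)` row-wise).
#' @return list with `p_value` and `odds_ratio`.
#' @export
fisher_exact <- function(table) {
  tab <- if (is.matrix(table)) table else matrix(table, 2, 2, byrow = TRUE)
  if (!all(dim(tab) == 2)) stop("need a 2 x 2 table")
  if (any(tab < 0) || any(tab != floor(tab)))
    stop("cells must be non-negative integers")
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; dd <- tab[2, 2]
  m1 <- a + b; m2 <- cc + dd; n1 <- a + cc; n2 <- b + dd
  if (m1 == 0 || m2 == 0 || n1 == 0 || n2 == 0)
    stop("all margins must be positive")
  support <- max(0, n1 - m2):min(n1, m1)
  logp <- stats::dhyper(support, m1, m2, n1, log = TRUE)
  obs <- logp[support == a]
  p <- sum(exp(logp[exp(logp) <= exp(obs) * (1 + 1e-7)]))
  p <- min(1, p)
  or <- if (any(tab == 0))
    ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5)) else (a * dd) / (b * cc)
  list(p_value = p, odds_ratio = or)
}

#' Enrichment of cell-specific loops among lost vs retained loops
#'
#' Builds the lost/retained x cell-specific/common `TwoByTwo` from a
#' WT-vs-mutant [classify_differential()] table (A = WT, so "lost" =
#' `A_specific` and "retained" = `common`) and per-loop specificity
#' labels, then tests it with Fisher's exact test.  The odds ratio answers
#' "how much likelier is a cell-specific loop to be lost than a common
#' loop".
#'
#' @param diff_table a `DifferentialLoopTable` (WT vs mutant).
#' @param specificity_labels character vector parallel to `diff_table`
#'   rows with values `"cell_specific"` or `"common"` (loops classified
#'   `neither`/`B_specific` are ignored, but every lost/retained loop must
#'   be labeled).
#' @return a [two_by_two()] with rows lost/retained and columns
#'   cell-specific/common.
#' @export
cell_specific_loss_enrichment <- function(diff_table, specificity_labels) {
  dt <- data.table::as.data.table(diff_table)
  if (length(specificity_labels) != nrow(dt))
    stop("one specificity label per loop required")
  rel <- dt$class %in% c("A_specific", "common")
  lab <- specificity_labels[rel]
  if (anyNA(lab) || !all(lab %in% c("cell_specific", "common")))
    stop("every lost/retained loop must be labeled cell_specific or common")
  lost <- dt$class[rel] == "A_specific"
  two_by_two(sum(lost & lab == "cell_specific"),
             sum(lost & lab == "common"),
             sum(!lost & lab == "cell_specific"),
             sum(!lost & lab == "common"),
             groups = c("lost", "retained"),
             properties = c("cell_specific", "common"))
}

#' Strand-aware gene test intervals: body extended upstream
#'
#' `[min(tss, tes), max(tss, tes))` extended by `upstream` bp 5' of the
#' TSS: to the left for plus-strand genes, to the right for minus-strand
#' genes.
#'
#' @param genes gene table (`id`, `chrom`, `strand`, `tss`, `tes`).
#' @param upstream upstream extension in bp (default 1000).
#' @return data.table with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
gene_test_intervals <- function(genes, upstream = 1000) {
  g <- data.table::as.data.table(genes)
  data.table::data.table(
    chrom = g$chrom,
    start = pmax(0, pmin(g$tss, g$tes) - ifelse(g$strand == "+", upstream, 0)),
    end = pmax(g$tss, g$tes) + ifelse(g$strand == "-", upstream, 0),
    name = g$id, strand = g$strand)
}

#' CTCF binding at a gene set
#'
#' Flags each gene whose body extended `upstream` bp 5' of the TSS
#' (strand-aware) overlaps a peak by >= 1 bp, and reports the bound
#' fraction.  Genes missing from the model table are skipped and reported.
#'
#' @param gene_ids character vector of gene ids to test.
#' @param genes gene table providing the models.
#' @param peaks peak intervals (`chrom`, `start`, `end`).
#' @param upstream upstream extension in bp (default 1000).
#' @return list with `fraction` (bound / tested), `flags` (named logical
#'   per tested gene), `n_skipped` (ids without a model).
#' @export
gene_ctcf_overlap <- function(gene_ids, genes, peaks, upstream = 1000) {
  g <- data.table::as.data.table(genes)
  found <- gene_ids %in% g$id
  sub <- g[match(gene_ids[found], id)]
  iv <- gene_test_intervals(sub, upstream)
  flags <- overlap_any(iv[, .(chrom, start, end)], peaks)
  names(flags) <- sub$id
  list(fraction = if (length(flags)) mean(flags) else NA_real_,
       flags = flags, n_skipped = sum(!found))
}

#' Seeded random gene sets from a universe
#'
#' Draws `n_sets` size-matched gene sets without replacement, for
#' enrichment nulls ("randomly generated lists of genes").
#'
#' @param universe character vector of candidate gene ids.
#' @param size genes per set.
#' @param n_sets number of sets (default 2).
#' @param seed integer seed; identical inputs give identical sets.
#' @param exclude optional ids removed from the universe first (e.g. the
#'   query set).
#' @return list of character vectors.
#' @export
random_gene_sets <- function(universe, size, n_sets = 2L, seed = 1L,
                             exclude = NULL) {
  pool <- setdiff(universe, exclude)
  if (size > length(pool)) stop("size exceeds the (remaining) universe")
  with_seed(seed, lapply(seq_len(n_sets), function(k) sample(pool, size)))
}

#' Gene colocalization with loops, with a random-set null
#'
#' Flags genes whose body overlaps a loop (anchor mode: either anchor's
#' bin interval; span mode: the full `[anchor_i start, anchor_j end)`
#' interval), and compares the query fraction against size-matched random
#' gene sets with Fisher's exact test (query bound/unbound vs pooled
#' random bound/unbound).
#'
#' @param gene_ids query gene ids.
#' @param genes gene table (the universe, with models).
#' @param loops `LoopSet` or data.table with `chrom`, `bin_i`, `bin_j`.
#' @param genome a [binned_genome()]; taken from a `LoopSet` input.
#' @param mode `"anchor"` (default) or `"span"`.
#' @param n_random random null sets (default 2).
#' @param seed seed for the null draws.
#' @return list with `fraction`, `flags` (named, per query gene),
#'   `random_fractions`, `test` (a [two_by_two()] of query vs pooled
#'   random, or NULL when a zero table margin makes the test undefined),
#'   `mode`, `seed`.
#' @export
gene_loop_colocalization <- function(gene_ids, genes, loops, genome = NULL,
                                     mode = c("anchor", "span"),
                                     n_random = 2L, seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(loops, "LoopSet")) {
    genome <- loops$genome
    loops <- loops$loops
  }
  stopifnot(inherits(genome, "BinnedGenome"))
  lp <- data.table::as.data.table(loops)
  bs <- genome$bin_size
  target <- if (mode == "anchor") rbind(
    lp[, .(chrom, start = bin_i * bs, end = (bin_i + 1) * bs)],
    lp[, .(chrom, start = bin_j * bs, end = (bin_j + 1) * bs)]) else
    lp[, .(chrom, start = bin_i * bs, end = (bin_j + 1) * bs)]
  g <- data.table::as.data.table(genes)
  bodies <- gene_bodies(g)
  all_flags <- stats::setNames(
    overlap_any(bodies[, .(chrom, start, end)], target), g$id)
  flag_of <- function(ids) all_flags[ids]
  qf <- flag_of(gene_ids)
  nulls <- random_gene_sets(g$id, length(gene_ids), n_random, seed)
  nf <- lapply(nulls, flag_of)
  pooled <- unlist(nf)
  # a zero margin (nothing colocalized anywhere, or everything) makes the
  # Fisher test undefined; report NULL rather than erroring
  tst <- tryCatch(
    two_by_two(sum(qf), sum(!qf), sum(pooled), sum(!pooled),
               groups = c("query", "random"),
               properties = c("colocalized", "not")),
    error = function(e) NULL)
  list(fraction = mean(qf), flags = qf,
       random_fractions = vapply(nf, mean, numeric(1)),
       test = tst, mode = mode, seed = seed)
}

#' Regulatory annotation of loop anchors
#'
#' Flags each anchor bin for promoter and enhancer overlap and assigns a
#' per-loop category: `P-P`, `P-E`, `E-E` when both anchors are annotated
#' (an anchor overlapping both counts as promoter first, matching the
#' two-anchor categories), `P (one anchor)` / `E (one anchor)` when only
#' one is, `none` otherwise.
#'
#' @param loops `LoopSet` or data.table with `chrom`, `bin_i`, `bin_j`.
#' @param promoters,enhancers interval tables (`chrom`, `start`, `end`).
#' @param genome a [binned_genome()]; taken from a `LoopSet` input.
#' @return data.table: loop coordinates, per-anchor flags
#'   (`promoter_left`, `enhancer_left`, `promoter_right`,
#'   `enhancer_right`) and `category`.
#' @export
annotate_regulatory_anchors <- function(loops, promoters, enhancers,
                                        genome = NULL) {
  if (inherits(loops, "LoopSet")) {
    genome <- loops$genome
    loops <- loops$loops
  }
  stopifnot(inherits(genome, "BinnedGenome"))
  lp <- data.table::as.data.table(loops)
  bs <- genome$bin_size
  anchor <- function(bin) data.table::data.table(
    chrom = lp$chrom, start = bin * bs, end = (bin + 1) * bs)
  out <- lp[, .(chrom, bin_i, bin_j)]
  out[, `:=`(promoter_left = overlap_any(anchor(lp$bin_i), promoters),
             enhancer_left = overlap_any(anchor(lp$bin_i), enhancers),
             promoter_right = overlap_any(anchor(lp$bin_j), promoters),
             enhancer_right = overlap_any(anchor(lp$bin_j), enhancers))]
  lab <- function(p, e) data.table::fcase(p, "P", e, "E", default = "none")
  l <- lab(out$promoter_left, out$enhancer_left)
  r <- lab(out$promoter_right, out$enhancer_right)
  out[, category := data.table::fcase(
    l == "none" & r == "none", "none",
    l == "none" | r == "none",
      sprintf("%s (one anchor)", ifelse(l == "none", r, l)),
    default = paste(pmax(l, r), pmin(l, r), sep = "-"))]  # P sorts after E
  out[]
}

#' Promoter windows around TSS
#'
#' `[TSS - window, TSS + window)` per gene, clipped at 0.
#'
#' @param genes gene table.
#' @param window half-width in bp (default 1000: TSS +- 1 kb).
#' @return data.table with `chrom`, `start`, `end`, `name`, `strand`.
#' @export
promoter_windows <- function(genes, window = 1000) {
  g <- data.table::as.data.table(genes)
  data.table::data.table(chrom = g$chrom, start = pmax(0, g$tss - window),
                         end = g$tss + window, name = g$id, strand = g$strand)
}

#' Three-way candidate-RNA intersection
#'
#' Intersects (i) upregulated genes, (ii) genes colocalized at loop
#' anchors, and (iii) condition-specific CLIP genes; candidates are the
#' triple intersection.  When loops are supplied, each candidate is linked
#' to the anchors its body overlaps.
#'
#' @param upregulated,loop_colocalized,clip_specific character vectors of
#'   gene ids over one universe.
#' @param genes optional gene table (required for anchor linking).
#' @param loops optional `LoopSet`/data.table of the loops used for
#'   colocalization.
#' @param genome a [binned_genome()] (taken from a `LoopSet`).
#' @return An object of class `CandidateReport`: list with `sets`,
#'   `pairwise` (named intersection sizes), `candidates` (sorted ids),
#'   `n_candidates`, `linked_anchors` (data.table gene/chrom/bin) and
#'   `n_linked_anchors`.
#' @export
candidate_rnas <- function(upregulated, loop_colocalized, clip_specific,
                           genes = NULL, loops = NULL, genome = NULL) {
  up <- unique(upregulated); co <- unique(loop_colocalized)
  cl <- unique(clip_specific)
  cand <- sort(intersect(intersect(up, co), cl))
  linked <- data.table::data.table(gene = character(), chrom = character(),
                                   bin = integer())
  if (!is.null(genes) && !is.null(loops) && length(cand)) {
    if (inherits(loops, "LoopSet")) {
      genome <- loops$genome
      loops <- loops$loops
    }
    stopifnot(inherits(genome, "BinnedGenome"))
    lp <- data.table::as.data.table(loops)
    bs <- genome$bin_size
    anchors <- unique(rbind(lp[, .(chrom, bin = bin_i)],
                            lp[, .(chrom, bin = bin_j)]))
    g <- data.table::as.data.table(genes)
    bodies <- gene_bodies(g[id %in% cand])
    rows <- list()
    for (k in seq_len(nrow(bodies))) {
      hit <- anchors[chrom == bodies$chrom[k] &
                       bin * bs < bodies$end[k] &
                       (bin + 1) * bs > bodies$start[k]]
      if (nrow(hit))
        rows[[length(rows) + 1]] <- data.table::data.table(
          gene = bodies$name[k], chrom = hit$chrom, bin = hit$bin)
    }
    if (length(rows)) linked <- data.table::rbindlist(rows)
  }
  structure(list(
    sets = list(upregulated = up, loop_colocalized = co, clip_specific = cl),
    pairwise = c(up_coloc = length(intersect(up, co)),
                 up_clip = length(intersect(up, cl)),
                 coloc_clip = length(intersect(co, cl))),
    candidates = cand, n_candidates = length(cand),
    linked_anchors = unique(linked),
    n_linked_anchors = nrow(unique(linked))),
    class = "CandidateReport")
}

#' @export
print.CandidateReport <- function(x, ...) {
  cat(sprintf(paste0("CandidateReport: %d candidates from sets of %d/%d/%d ",
                     "(up/coloc/clip); %d linked anchors\n"),
              x$n_candidates, length(x$sets$upregulated),
              length(x$sets$loop_colocalized), length(x$sets$clip_specific),
              x$n_linked_anchors))
  invisible(x)
}
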