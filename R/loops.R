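#' Benjamini-Hochberg adjustment with an explicit family size
#'
#' Computes `q_i = min over j with p_(j) >= p_(i) of m * p_(j) / rank_j`,
#' capped at 1.  `m` may exceed `length(p)` when the tested family includes
#' members whose p-values are implicitly 1 (e.g. zero-count bin pairs in a
#' distance band): those contribute only their count, since `m * 1 / m = 1`
#' never lowers any q.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param m family size (default `length(p)`; must be `>= length(p)`).
#' @return numeric vector of q-values, same order as `p`.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04, 0.8))
bh_adjust <- function(p, m = length(p)) {
  if (length(p) == 0) return(numeric(0))
  if (anyNA(p) || any(is.nan(p))) stop("p-values must not be NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (m < length(p)) stop("family size m must be >= length(p)")
  ord <- order(p)
  ranked <- pmin(1, m * p[ord] / seq_along(p))
  q <- rev(cummin(rev(ranked)))
  out <- numeric(length(p))
  out[ord] <- q
  out
}

#' Distance-stratified loop calling on a contact map
#'
#' For every intra-chromosomal bin pair at separation `min_sep <= d <=
#' max_sep`, the observed count `k` is tested against the map's
#' distance-decay expectation: `p = P(X >= k)` for
#' `X ~ Binomial(N, p_d)` with `N` the map's total valid pairs and
#' `p_d = E(d) / N` from the supplied [expected_by_distance()] profile.
#' q-values are Benjamini-Hochberg over all tested pairs in the band --
#' zero-count pairs are counted in the family size `m` (their p-values are
#' implicitly 1).  Loops are the pairs with `q <= fdr`.
#'
#' @param map a [contact_map()].
#' @param profile a raw-count [expected_by_distance()] profile computed
#'   from the same map (or its condition).
#' @param fdr q-value threshold (default 0.01).
#' @param min_sep,max_sep tested separation band in bins (defaults 2 and
#'   400; `max_sep` beyond the chromosome span is clipped with a warning).
#' @param condition optional condition label recorded on the output.
#' @return An object of class `LoopSet`: list with `loops` (data.table
#'   `chrom`, `bin_i`, `bin_j`, `d`, `k`, `mu`, `p_value`, `q_value`),
#'   `tests` (the same columns for every nonzero-count pair in the band),
#'   `m` (BH family size), `n_valid_pairs`, `genome`, `resolution`, `fdr`,
#'   `min_sep`, `max_sep` and `condition`.
#' @export
call_loops <- function(map, profile, fdr = 0.01, min_sep = 2L, max_sep = 400L,
                       condition = NA_character_) {
  stopifnot(inherits(map, "ContactMap"), inherits(profile, "DecayProfile"))
  if (isTRUE(attr(profile, "balanced")))
    stop("call_loops requires a raw-count (unbalanced) DecayProfile")
  if (min_sep < 1 || max_sep < min_sep) stop("need 1 <= min_sep <= max_sep")
  g <- map$genome
  span <- max(g$n_bins) - 1L
  if (max_sep > span) {
    warning(sprintf("max_sep %d exceeds chromosome span; clipped to %d",
                    max_sep, span))
    max_sep <- span
  }
  N <- map$total_valid_pairs
  # expected count by distance, indexed d + 1
  Ed <- numeric(max_sep + 1L)
  Ed[profile$d[profile$d <= max_sep] + 1L] <-
    profile$expected[profile$d <= max_sep]
  # family size: all pairs in the band, zero-count included
  m <- 0
  for (cn in g$chrom) {
    n <- g$n_bins[[cn]]
    dd <- min_sep:min(max_sep, n - 1L)
    m <- m + sum(n - dd)
  }
  tests <- map$triplets[bin_j - bin_i >= min_sep & bin_j - bin_i <= max_sep,
                        .(chrom, bin_i, bin_j, count)]
  tests[, d := bin_j - bin_i]
  tests[, mu := Ed[d + 1L]]
  tests[, p_value := stats::pbinom(count - 1, size = N, prob = mu / N,
                                   lower.tail = FALSE)]
  tests[, q_value := bh_adjust(p_value, m = m)]
  data.table::setnames(tests, "count", "k")
  data.table::setcolorder(tests, c("chrom", "bin_i", "bin_j", "d", "k", "mu",
                                   "p_value", "q_value"))
  data.table::setkey(tests, chrom, bin_i, bin_j)
  structure(list(loops = tests[q_value <= fdr], tests = tests, m = m,
                 n_valid_pairs = N, genome = g, resolution = g$bin_size,
                 fdr = fdr, min_sep = as.integer(min_sep),
                 max_sep = as.integer(max_sep), condition = condition),
            class = "LoopSet")
}

#' @export
print.LoopSet <- function(x, ...) {
  cat(sprintf("LoopSet: %d loops at q <= %g (%d pairs tested, family m = %.0f)%s\n",
              nrow(x$loops), x$fdr, nrow(x$tests), x$m,
              if (is.na(x$condition)) "" else paste0(" [", x$condition, "]")))
  invisible(x)
}

#' Differential (sample-specific / common) loop classification
#'
#' Applies the two-sample rule over the union of bin pairs significant in
#' either input: a pair is `A_specific` iff `q_A <= fdr`, `q_B > fdr` and
#' `log2FC <= -lfc` where `log2FC = log2((k_B + pc) / (k_A + pc))`;
#' `B_specific` symmetrically; `common` iff significant in both (regardless
#' of fold change); `neither` otherwise.  When A is wild type and B the
#' mutant, "lost" loops are the `A_specific` class and "retained" loops the
#' `common` class.
#'
#' @param callsA,callsB [call_loops()] results on depth-matched
#'   (downsampled) maps.  Unequal valid-pair totals trigger a warning, not
#'   an error.
#' @param fdr significance threshold on both q-values (default 0.01).
#' @param lfc absolute log2 fold-change stringency (default 1).
#' @param pc pseudocount for the fold change (default 1; recorded).
#' @return An object of class `DifferentialLoopTable`: data.table with
#'   columns `chrom`, `bin_i`, `bin_j`, `d`, `k_A`, `k_B`, `q_A`, `q_B`,
#'   `log2FC`, `class`; attributes `fdr`, `lfc`, `pc`.
#' @export
classify_differential <- function(callsA, callsB, fdr = 0.01, lfc = 1, pc = 1) {
  stopifnot(inherits(callsA, "LoopSet"), inherits(callsB, "LoopSet"))
  if (!same_genome(callsA$genome, callsB$genome))
    stop("loop sets must share one BinnedGenome")
  if (pc <= 0) stop("pseudocount pc must be > 0")
  if (callsA$n_valid_pairs != callsB$n_valid_pairs)
    warning("valid-pair totals differ; classify on downsampled maps")
  sigA <- callsA$tests[q_value <= fdr, .(chrom, bin_i, bin_j)]
  sigB <- callsB$tests[q_value <= fdr, .(chrom, bin_i, bin_j)]
  u <- unique(rbind(sigA, sigB))
  a <- callsA$tests[u, on = c("chrom", "bin_i", "bin_j")]
  b <- callsB$tests[u, on = c("chrom", "bin_i", "bin_j")]
  out <- data.table::data.table(
    chrom = u$chrom, bin_i = u$bin_i, bin_j = u$bin_j,
    d = u$bin_j - u$bin_i,
    k_A = data.table::fifelse(is.na(a$k), 0, a$k),
    k_B = data.table::fifelse(is.na(b$k), 0, b$k),
    q_A = data.table::fifelse(is.na(a$q_value), 1, a$q_value),
    q_B = data.table::fifelse(is.na(b$q_value), 1, b$q_value))
  out[, log2FC := log2((k_B + pc) / (k_A + pc))]
  out[, class := data.table::fcase(
    q_A <= fdr & q_B <= fdr, "common",
    q_A <= fdr & q_B > fdr & log2FC <= -lfc, "A_specific",
    q_B <= fdr & q_A > fdr & log2FC >= lfc, "B_specific",
    default = "neither")]
  data.table::setkey(out, chrom, bin_i, bin_j)
  structure(out, class = c("DifferentialLoopTable", class(out)),
            fdr = fdr, lfc = lfc, pc = pc)
}

#' Annotate loop anchors by peak overlap
#'
#' Each anchor's bin interval `[bin * bin_size, (bin + 1) * bin_size)`,
#' padded by `pad` bp on each side, is tested for >= 1 bp overlap with the
#' peak set (half-open arithmetic).  A "CTCF loop anchor" is a loop with
#' both flags true.
#'
#' @param loops a [call_loops()] `LoopSet` or a data.table with `chrom`,
#'   `bin_i`, `bin_j`.
#' @param ctcf_peaks interval data.table (`chrom`, `start`, `end`).
#' @param cohesin_peaks optional second peak set, flagged analogously.
#' @param pad padding in bp on each anchor side (default 0).
#' @param genome a [binned_genome()]; taken from `loops` when it is a
#'   `LoopSet`.
#' @return data.table: loop coordinates plus `ctcf_left`, `ctcf_right`,
#'   `ctcf_anchor` (both), and `cohesin_left`/`cohesin_right`/
#'   `cohesin_anchor` when supplied.
#' @export
annotate_anchors <- function(loops, ctcf_peaks, cohesin_peaks = NULL, pad = 0,
                             genome = NULL) {
  if (inherits(loops, "LoopSet")) {
    genome <- loops$genome
    loops <- loops$loops
  }
  stopifnot(inherits(genome, "BinnedGenome"))
  lp <- data.table::as.data.table(loops)
  bs <- genome$bin_size
  anchor_iv <- function(bin) data.table::data.table(
    chrom = lp$chrom, start = pmax(0, bin * bs - pad), end = (bin + 1) * bs + pad)
  out <- lp[, .(chrom, bin_i, bin_j)]
  out[, `:=`(ctcf_left = overlap_any(anchor_iv(lp$bin_i), ctcf_peaks),
             ctcf_right = overlap_any(anchor_iv(lp$bin_j), ctcf_peaks))]
  out[, ctcf_anchor := ctcf_left & ctcf_right]
  if (!is.null(cohesin_peaks)) {
    out[, `:=`(cohesin_left = overlap_any(anchor_iv(lp$bin_i), cohesin_peaks),
               cohesin_right = overlap_any(anchor_iv(lp$bin_j), cohesin_peaks))]
    out[, cohesin_anchor := cohesin_left & cohesin_right]
  }
  out[]
}

#' Genomic span of loops in bp
#'
#' @param loops a `LoopSet` or data.table with `bin_i`, `bin_j`.
#' @param bin_size bin width in bp; taken from the `LoopSet` if given.
#' @return numeric vector `(bin_j - bin_i) * bin_size`, one per loop.
#' @export
loop_span_lengths <- function(loops, bin_size = NULL) {
  if (inherits(loops, "LoopSet")) {
    bin_size <- loops$genome$bin_size
    loops <- loops$loops
  }
  stopifnot(!is.null(bin_size))
  lp <- data.table::as.data.table(loops)
  if (nrow(lp) == 0) return(numeric(0))
  (lp$bin_j - lp$bin_i) * bin_size
}

#' Write loops as BEDPE
#'
#' Ten standard columns (`chrom1 start1 end1 chrom2 start2 end2 name score
#' strand1 strand2`) plus any extra statistic columns (`k`, `mu`,
#' `p_value`, `q_value`, `class`, ...), with a `#`-prefixed header line.
#'
#' @param loops a `LoopSet`, `DifferentialLoopTable` or data.table with
#'   `chrom`, `bin_i`, `bin_j`.
#' @param path output path.
#' @param genome a [binned_genome()]; taken from a `LoopSet` input.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path, genome = NULL) {
  if (inherits(loops, "LoopSet")) {
    genome <- loops$genome
    loops <- loops$loops
  }
  stopifnot(inherits(genome, "BinnedGenome"))
  lp <- data.table::as.data.table(loops)
  bs <- genome$bin_size
  extra <- setdiff(names(lp), c("chrom", "bin_i", "bin_j"))
  out <- data.table::data.table(
    chrom1 = lp$chrom, start1 = lp$bin_i * bs, end1 = (lp$bin_i + 1) * bs,
    chrom2 = lp$chrom, start2 = lp$bin_j * bs, end2 = (lp$bin_j + 1) * bs,
    name = sprintf("loop_%d", seq_len(nrow(lp))), score = 0,
    strand1 = ".", strand2 = ".")
  for (col in extra) out[, (col) := lp[[col]]]
  writeLines(paste0("#", paste(names(out), collapse = "\t")), path)
  if (nrow(out))
    data.table::fwrite(out, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a BEDPE loop file written by [write_bedpe()]
#'
#' @param path file path.
#' @param genome a [binned_genome()] used to convert coordinates back to
#'   bins and validate them.
#' @return data.table with `chrom`, `bin_i`, `bin_j` plus any extra
#'   columns.
#' @export
read_bedpe <- function(path, genome) {
  stopifnot(inherits(genome, "BinnedGenome"))
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#"))
    stop("BEDPE file must start with a '#' header line")
  cols <- strsplit(sub("^#", "", lines[1]), "\t", fixed = TRUE)[[1]]
  body <- which(nzchar(trimws(lines)))[-1]
  if (!length(body))
    return(data.table::data.table(chrom = character(), bin_i = integer(),
                                  bin_j = integer()))
  parts <- strsplit(lines[body], "\t", fixed = TRUE)
  bad <- which(lengths(parts) != length(cols))
  if (length(bad)) parse_error(path, body[bad[1]], "wrong number of fields")
  dt <- data.table::as.data.table(do.call(rbind, parts))
  data.table::setnames(dt, cols)
  for (col in setdiff(cols, c("chrom1", "chrom2", "name", "strand1", "strand2", "class")))
    dt[, (col) := suppressWarnings(as.numeric(get(col)))]
  bad <- which(is.na(dt$start1) | is.na(dt$start2))
  if (length(bad)) parse_error(path, body[bad[1]], "malformed coordinates")
  bad <- which(!(dt$chrom1 %in% genome$chrom) | !(dt$chrom2 %in% genome$chrom))
  if (length(bad)) parse_error(path, body[bad[1]], "unknown chromosome")
  bad <- which(dt$chrom1 != dt$chrom2)
  if (length(bad)) parse_error(path, body[bad[1]],
                               "inter-chromosomal loops not supported")
  out <- data.table::data.table(
    chrom = dt$chrom1,
    bin_i = as.integer(dt$start1 %/% genome$bin_size),
    bin_j = as.integer(dt$start2 %/% genome$bin_size))
  for (col in setdiff(cols, c("chrom1", "start1", "end1", "chrom2", "start2",
                              "end2", "name", "score", "strand1", "strand2")))
    out[, (col) := dt[[col]]]
  out[]
}
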