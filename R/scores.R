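# dense symmetric matrix of one chromosome's (optionally balanced) counts;
# rows/cols of missing bins (NA weight) are NA
balanced_dense <- function(map, chrom, weights = NULL) {
  n <- map$genome$n_bins[[chrom]]
  M <- as.matrix(chrom_sparse(map, chrom, weights))
  if (!is.null(weights)) {
    wv <- weight_vector(weights, chrom, n)
    M[is.na(wv), ] <- NA_real_
    M[, is.na(wv)] <- NA_real_
  }
  unname(M)
}

# expected-value lookup vector indexed by d + 1 (NA where undefined)
expected_lookup <- function(profile, max_d) {
  Ed <- rep(NA_real_, max_d + 1L)
  sel <- profile$d <= max_d
  Ed[profile$d[sel] + 1L] <- profile$expected[sel]
  Ed
}

#' Observed-over-expected matrix for one chromosome
#'
#' Balanced counts divided by the distance expectation
#' `E(d)` of the supplied profile (which must match the balancing state:
#' a profile computed with the same weights).  Missing bins give NA
#' rows/columns; distances with no defined expectation give NA.
#'
#' @param map a [contact_map()].
#' @param chrom chromosome name.
#' @param weights optional [ice_balance()] weights.
#' @param profile an [expected_by_distance()] profile computed with the
#'   same `weights`.
#' @return dense symmetric numeric matrix (bins x bins, 0-based bin `b` at
#'   row/column `b + 1`).
#' @export
oe_matrix <- function(map, chrom, weights = NULL, profile) {
  stopifnot(inherits(map, "ContactMap"), inherits(profile, "DecayProfile"))
  if (!identical(isTRUE(attr(profile, "balanced")), !is.null(weights)))
    stop("profile balancing state must match the supplied weights")
  n <- map$genome$n_bins[[chrom]]
  M <- balanced_dense(map, chrom, weights)
  Ed <- expected_lookup(profile, n - 1L)
  D <- abs(outer(seq_len(n), seq_len(n), "-"))
  M / matrix(Ed[D + 1L], n, n)
}

#' Aggregate peak analysis (APA)
#'
#' Averages the (2w+1) x (2w+1) observed/expected window centered on each
#' loop pixel `(i, j)` (rows follow the first anchor `i`, columns the
#' second anchor `j`), then scores the aggregate as center value over the
#' mean of the `corner` x `corner` "lower-left" block (rows nearest the
#' `i + w` edge, columns nearest the `j - w` edge) -- the corner closest to
#' the diagonal, as in Juicer's APA score.  Loops whose window would cross
#' the diagonal (`j - i <= 2w`), leave the chromosome, or touch a missing
#' bin are skipped and counted.
#'
#' @inheritParams oe_matrix
#' @param loops a `LoopSet` or data.table with `chrom`, `bin_i`, `bin_j`.
#' @param w window half-width in bins (default 10: a 21 x 21 window).
#' @param corner corner block size in bins (default 6).
#' @return An object of class `ApaResult`: list with `aggregate` (matrix),
#'   `score`, `center_values` (per used loop), `n_used`, `n_skipped`, `w`,
#'   `corner`.
#' @export
apa <- function(map, weights = NULL, profile, loops, w = 10L, corner = 6L) {
  if (inherits(loops, "LoopSet")) loops <- loops$loops
  lp <- data.table::as.data.table(loops)
  k <- 2L * w + 1L
  agg <- matrix(0, k, k)
  centers <- numeric(0)
  used <- 0L; skipped <- 0L
  for (cn in unique(lp$chrom)) {
    OE <- oe_matrix(map, cn, weights, profile)
    n <- nrow(OE)
    sub <- lp[chrom == cn]
    for (r in seq_len(nrow(sub))) {
      i <- sub$bin_i[r]; j <- sub$bin_j[r]
      if (j - i <= 2L * w || i - w < 0L || j + w > n - 1L) {
        skipped <- skipped + 1L; next
      }
      S <- OE[(i - w):(i + w) + 1L, (j - w):(j + w) + 1L]
      if (anyNA(S)) { skipped <- skipped + 1L; next }
      agg <- agg + S
      centers <- c(centers, S[w + 1L, w + 1L])
      used <- used + 1L
    }
  }
  if (used == 0L) stop("no usable loops for APA")
  agg <- agg / used
  cor_rows <- (k - corner + 1L):k   # rows nearest the i + w edge
  cor_cols <- 1:corner              # columns nearest the j - w edge
  score <- agg[w + 1L, w + 1L] / mean(agg[cor_rows, cor_cols])
  structure(list(aggregate = agg, score = score, center_values = centers,
                 n_used = used, n_skipped = skipped, w = w, corner = corner),
            class = "ApaResult")
}

#' @export
print.ApaResult <- function(x, ...) {
  cat(sprintf("ApaResult: score %.3f over %d loops (%d skipped), window %dx%d\n",
              x$score, x$n_used, x$n_skipped, 2 * x$w + 1, 2 * x$w + 1))
  invisible(x)
}

#' Per-loop pixel enrichment over local background
#'
#' Center O/E divided by the mean O/E over the surrounding
#' (2w+1) x (2w+1) window excluding the central
#' (2 exclusion + 1)^2 block.  Loops too close to the diagonal or edge,
#' or with an undefined (zero/NA) background, give NA.
#'
#' @inheritParams apa
#' @param w window half-width (default 5).
#' @param exclusion half-width of the excluded center block (default 1,
#'   i.e. a 3 x 3 exclusion).
#' @return numeric vector of fold enrichments, one per loop; attribute
#'   `flagged` marks loops with undefined background.
#' @export
pixel_enrichment <- function(map, weights = NULL, profile, loops, w = 5L,
                             exclusion = 1L) {
  if (inherits(loops, "LoopSet")) loops <- loops$loops
  stopifnot(exclusion < w)
  lp <- data.table::as.data.table(loops)
  out <- rep(NA_real_, nrow(lp))
  flagged <- logical(nrow(lp))
  for (cn in unique(lp$chrom)) {
    OE <- oe_matrix(map, cn, weights, profile)
    n <- nrow(OE)
    idx <- which(lp$chrom == cn)
    for (r in idx) {
      i <- lp$bin_i[r]; j <- lp$bin_j[r]
      if (j - i <= 2L * w || i - w < 0L || j + w > n - 1L) next
      S <- OE[(i - w):(i + w) + 1L, (j - w):(j + w) + 1L]
      ring <- S
      ring[(w - exclusion):(w + exclusion) + 1L,
           (w - exclusion):(w + exclusion) + 1L] <- NA
      bg <- mean(ring, na.rm = TRUE)
      if (!is.finite(bg) || bg == 0) { flagged[r] <- TRUE; next }
      out[r] <- S[w + 1L, w + 1L] / bg
    }
  }
  structure(out, flagged = flagged)
}

# summed-area table with NA treated as 0; also returns the count of
# non-NA cells for mean computations
sat <- function(M) {
  V <- M; V[is.na(V)] <- 0
  list(sum = apply(apply(rbind(0, cbind(0, V)), 2, cumsum), 1, cumsum),
       cnt = apply(apply(rbind(0, cbind(0, !is.na(M))), 2, cumsum), 1, cumsum))
}

# sum over M[r1:r2, c1:c2] from a summed-area table (1-based, inclusive)
sat_query <- function(S, r1, r2, c1, c2) {
  S[cbind(c2 + 1L, r2 + 1L)] - S[cbind(c2 + 1L, r1)] -
    S[cbind(c1, r2 + 1L)] + S[cbind(c1, r1)]
}

#' Diamond insulation score and boundary calls
#'
#' For each bin `i`, the raw value is the mean balanced contact value over
#' the diamond `{(a, b): i - window < a <= i < b <= i + window}` (defined
#' only where the full diamond fits inside the chromosome and touches no
#' missing bin); the insulation score is `log2(raw / chromosome mean
#' raw)`.  Boundaries are local score minima with topographic prominence
#' of at least `min_prominence`; lower scores mark stronger boundaries.
#'
#' @param map a [contact_map()].
#' @param weights [ice_balance()] weights (NULL for raw counts).
#' @param window diamond size in bins (default 10; must be >= 2).
#' @param min_prominence boundary prominence threshold (default 0.1).
#' @return An object of class `InsulationTrack`: data.table with `chrom`,
#'   `bin`, `raw`, `score`, `boundary`, `prominence`; attributes `window`
#'   and `min_prominence`.
#' @export
insulation <- function(map, weights = NULL, window = 10L,
                       min_prominence = 0.1) {
  stopifnot(inherits(map, "ContactMap"), window >= 2)
  g <- map$genome
  out <- vector("list", length(g$chrom))
  for (ci in seq_along(g$chrom)) {
    cn <- g$chrom[ci]
    n <- g$n_bins[[cn]]
    M <- balanced_dense(map, cn, weights)
    S <- sat(M)
    raw <- rep(NA_real_, n)
    ii <- window:(n - window)          # 1-based center rows with full diamond
    r1 <- ii - window + 1L; r2 <- ii; c1 <- ii + 1L; c2 <- ii + window
    tot <- sat_query(S$sum, r1, r2, c1, c2)
    cnt <- sat_query(S$cnt, r1, r2, c1, c2)
    raw[ii] <- ifelse(cnt == window^2, tot / window^2, NA_real_)
    mu <- mean(raw, na.rm = TRUE)
    score <- ifelse(!is.na(raw) & raw > 0 & mu > 0, log2(raw / mu), NA_real_)
    prom <- prominence_of_minima(score)
    out[[ci]] <- data.table::data.table(
      chrom = cn, bin = 0:(n - 1L), raw = raw, score = score,
      prominence = prom, boundary = !is.na(prom) & prom >= min_prominence)
  }
  res <- data.table::rbindlist(out)
  data.table::setkey(res, chrom, bin)
  structure(res, class = c("InsulationTrack", class(res)),
            window = window, min_prominence = min_prominence)
}

# topographic prominence at local minima of a track (NA elsewhere):
# walk outward until a strictly lower value; prominence = min of the
# highest values reached on each side (boundary counts as a side maximum)
prominence_of_minima <- function(x) {
  n <- length(x)
  out <- rep(NA_real_, n)
  ok <- which(!is.na(x))
  if (length(ok) < 3) return(out)
  v <- x[ok]
  for (k in 2:(length(v) - 1)) {
    if (!(v[k] <= v[k - 1] && v[k] < v[k + 1])) next
    hi_l <- -Inf
    for (a in (k - 1):1) {
      if (v[a] < v[k]) break
      hi_l <- max(hi_l, v[a])
    }
    hi_r <- -Inf
    for (b in (k + 1):length(v)) {
      if (v[b] < v[k]) break
      hi_r <- max(hi_r, v[b])
    }
    out[ok[k]] <- min(hi_l, hi_r) - v[k]
  }
  out
}

#' Called boundary bins of an insulation track
#' @param track an [insulation()] result.
#' @return data.table with `chrom`, `bin`, `score`, `prominence`.
#' @export
boundaries <- function(track) {
  stopifnot(inherits(track, "InsulationTrack"))
  data.table::as.data.table(track)[boundary == TRUE,
                                   .(chrom, bin, score, prominence)]
}

# (2h+1) x (2h+1) mean filter with edge truncation, via summed-area table
smooth_matrix <- function(M, h) {
  if (h == 0) return(M)
  n <- nrow(M)
  S <- sat(M)
  idx <- seq_len(n)
  r1 <- pmax(1L, idx - h); r2 <- pmin(n, idx + h)
  out <- matrix(0, n, n)
  for (cc in idx) {
    c1 <- max(1L, cc - h); c2 <- min(n, cc + h)
    tot <- sat_query(S$sum, r1, r2, rep(c1, n), rep(c2, n))
    cnt <- (r2 - r1 + 1L) * (c2 - c1 + 1L)
    out[, cc] <- tot / cnt
  }
  out
}

#' Stratum-adjusted correlation coefficient (SCC) between two maps
#'
#' Both chromosomes' dense raw-count matrices are smoothed with a
#' (2h+1) x (2h+1) mean filter; for each distance stratum `d <=
#' max_dist_bins`, `rho_d` is the Pearson correlation of the paired
#' diagonal vectors; the per-chromosome SCC is the
#' `N_d * s_x,d * s_y,d`-weighted mean of the `rho_d` (zero-variance
#' strata excluded).
#'
#' @param mapA,mapB [contact_map()] objects over one genome.
#' @param h smoothing half-width (default 1).
#' @param max_dist_bins maximum stratum distance (default 400).
#' @return An object of class `SccResult`: list with `scc` (named
#'   per-chromosome vector), `strata` (data.table `chrom`, `d`, `n`,
#'   `rho`, `s_x`, `s_y`), `h`, `max_dist_bins`.
#' @export
scc <- function(mapA, mapB, h = 1L, max_dist_bins = 400L) {
  stopifnot(inherits(mapA, "ContactMap"), inherits(mapB, "ContactMap"))
  if (!same_genome(mapA$genome, mapB$genome))
    stop("maps must share one BinnedGenome")
  g <- mapA$genome
  res <- stats::setNames(rep(NA_real_, length(g$chrom)), g$chrom)
  strata <- vector("list", length(g$chrom))
  for (ci in seq_along(g$chrom)) {
    cn <- g$chrom[ci]
    n <- g$n_bins[[cn]]
    A <- smooth_matrix(balanced_dense(mapA, cn), h)
    B <- smooth_matrix(balanced_dense(mapB, cn), h)
    dd <- 1:min(max_dist_bins, n - 1L)
    st <- data.table::data.table(chrom = cn, d = dd, n = n - dd,
                                 rho = NA_real_, s_x = NA_real_,
                                 s_y = NA_real_)
    for (k in seq_along(dd)) {
      d <- dd[k]
      a <- seq_len(n - d)
      x <- A[cbind(a, a + d)]
      y <- B[cbind(a, a + d)]
      sx <- stats::sd(x); sy <- stats::sd(y)
      if (sx > 0 && sy > 0) {
        st[k, `:=`(rho = stats::cor(x, y), s_x = sx, s_y = sy)]
      }
    }
    use <- st[!is.na(rho)]
    if (nrow(use))
      res[ci] <- sum(use$n * use$s_x * use$s_y * use$rho) /
        sum(use$n * use$s_x * use$s_y)
    strata[[ci]] <- st
  }
  if (all(is.na(res))) stop("all strata degenerate; SCC undefined")
  structure(list(scc = res, strata = data.table::rbindlist(strata),
                 h = h, max_dist_bins = max_dist_bins),
            class = "SccResult")
}

#' @export
print.SccResult <- function(x, ...) {
  cat("SccResult:\n")
  for (cn in names(x$scc))
    cat(sprintf("  %s: SCC = %.4f\n", cn, x$scc[[cn]]))
  invisible(x)
}

# leading eigenvector of a symmetric positive semi-definite matrix by
# deterministic power iteration (fixed start), falling back to eigen()
leading_eigenvector <- function(C, tol = 1e-10, max_iter = 2000L) {
  n <- nrow(C)
  v <- (1 + 1e-3 * sin(seq_len(n)))
  v <- v / sqrt(sum(v^2))
  for (it in seq_len(max_iter)) {
    u <- as.numeric(C %*% v)
    nu <- sqrt(sum(u^2))
    if (nu == 0) break
    u <- u / nu
    if (1 - abs(sum(u * v)) < tol) return(u)
    v <- u
  }
  eigen(C, symmetric = TRUE)$vectors[, 1]
}

#' Compartment eigenvector (A/B compartments)
#'
#' Per chromosome: the O/E matrix is reduced to its Pearson correlation
#' matrix across bins; the leading eigenvector (largest eigenvalue) of
#' that symmetric matrix is the compartment track.  The global sign is
#' oriented so its correlation with `reference_track` is non-negative;
#' bins with positive values are labeled `A`, negative `B`.  Missing or
#' zero-variance bins get NA.
#'
#' @inheritParams oe_matrix
#' @param reference_track data.table (`chrom`, `bin`, `value`) used only
#'   to orient the sign (e.g. gene density or a known A-indicator).
#' @return An object of class `CompartmentTrack`: data.table with `chrom`,
#'   `bin`, `value` (unit-norm eigenvector per chromosome, NA for excluded
#'   bins), `label` (`A`/`B`/NA).
#' @export
compartment_eigenvector <- function(map, weights = NULL, profile,
                                    reference_track) {
  stopifnot(inherits(map, "ContactMap"))
  ref <- data.table::as.data.table(reference_track)
  stopifnot(all(c("chrom", "bin", "value") %in% names(ref)))
  g <- map$genome
  out <- vector("list", length(g$chrom))
  for (ci in seq_along(g$chrom)) {
    cn <- g$chrom[ci]
    n <- g$n_bins[[cn]]
    OE <- oe_matrix(map, cn, weights, profile)
    ok <- which(colSums(is.na(OE)) < n)            # bins not entirely NA
    if (length(ok) < 10) stop("fewer than 10 usable bins on ", cn)
    X <- OE[ok, ok, drop = FALSE]
    # cells undefined because E(d) = 0 (both observed and expected empty)
    # carry no signal; zero-fill so the fast complete-data path applies
    X[is.na(X)] <- 0
    keep <- colMeans(X^2) - colMeans(X)^2 > 0
    ok <- ok[keep]
    if (length(ok) < 10) stop("fewer than 10 usable bins on ", cn)
    X <- X[, keep, drop = FALSE]
    C <- suppressWarnings(stats::cor(X))
    if (anyNA(C)) stop("degenerate O/E correlation matrix on ", cn)
    v <- leading_eigenvector(C)
    rsub <- ref[.(cn, ok - 1L), on = c("chrom", "bin")]$value
    if (!anyNA(rsub) && stats::sd(rsub) > 0) {
      orient <- stats::cor(v, rsub)
      if (!is.na(orient) && orient < 0) v <- -v
    }
    val <- rep(NA_real_, n)
    val[ok] <- v
    out[[ci]] <- data.table::data.table(
      chrom = cn, bin = 0:(n - 1L), value = val,
      label = data.table::fcase(is.na(val), NA_character_,
                                val > 0, "A", val <= 0, "B"))
  }
  res <- data.table::rbindlist(out)
  data.table::setkey(res, chrom, bin)
  structure(res, class = c("CompartmentTrack", class(res)))
}

#' Mean per-bin track profile around sites
#'
#' Averages a per-bin track at signed bin offsets `-flank_bins ..
#' +flank_bins` from each site's center bin.
#'
#' @param track data.table with `chrom`, `bin` and a value column named
#'   `score` or `value`.
#' @param sites interval data.table (`chrom`, `start`, `end` in bp).
#' @param flank_bins flank width in bins.
#' @param genome a [binned_genome()].
#' @return data.table with `offset`, `mean_value`, `n` (sites contributing
#'   a non-NA value at that offset).
#' @export
profile_at_sites <- function(track, sites, flank_bins, genome) {
  stopifnot(inherits(genome, "BinnedGenome"))
  st <- data.table::as.data.table(sites)
  if (nrow(st) == 0) stop("empty site list")
  check_chrom(genome, st$chrom)
  tr <- data.table::as.data.table(track)
  vcol <- intersect(c("score", "value"), names(tr))[1]
  if (is.na(vcol)) stop("track needs a 'score' or 'value' column")
  centers <- bin_index(genome, st$chrom, (st$start + st$end) %/% 2)
  offs <- -flank_bins:flank_bins
  lookup <- tr[, .(chrom, bin, v = get(vcol))]
  data.table::setkey(lookup, chrom, bin)
  out <- data.table::data.table(offset = offs, mean_value = NA_real_, n = 0L)
  for (k in seq_along(offs)) {
    q <- data.table::data.table(chrom = st$chrom, bin = centers + offs[k])
    vals <- lookup[q, on = c("chrom", "bin")]$v
    out[k, `:=`(mean_value = mean(vals, na.rm = TRUE),
                n = sum(!is.na(vals)))]
  }
  out[]
}
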