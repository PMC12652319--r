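#' Contact map container
#'
#' A `ContactMap` stores the upper triangle of a binned intra-chromosomal
#' contact matrix as triplets `(chrom, bin_i, bin_j, count)` with
#' `bin_i <= bin_j` (0-based per-chromosome bin indices).  Entries supplied
#' with `bin_i > bin_j` are transposed and merged by summation, so all
#' consumers see a symmetric matrix.  Inter-chromosomal pairs are not
#' represented.
#'
#' @param genome a [binned_genome()].
#' @param triplets a data.frame/data.table with columns `chrom`, `bin_i`,
#'   `bin_j`, `count`.
#' @return An object of class `ContactMap`: list with `genome`, `triplets`
#'   (a keyed `data.table`) and `total_valid_pairs`.
#' @export
contact_map <- function(genome, triplets) {
  stopifnot(inherits(genome, "BinnedGenome"))
  dt <- data.table::as.data.table(triplets)
  need <- c("chrom", "bin_i", "bin_j", "count")
  if (!all(need %in% names(dt)))
    stop("triplets must have columns: ", paste(need, collapse = ", "))
  dt <- dt[, .(chrom = as.character(chrom), bin_i = as.integer(bin_i),
               bin_j = as.integer(bin_j), count = as.numeric(count))]
  if (nrow(dt)) {
    check_chrom(genome, dt$chrom)
    if (any(dt$count < 0)) stop("negative contact counts")
    if (any(dt$count != floor(dt$count))) stop("non-integer contact counts")
    nb <- genome$n_bins[dt$chrom]
    if (any(dt$bin_i < 0) || any(dt$bin_j < 0) ||
        any(dt$bin_i >= nb) || any(dt$bin_j >= nb))
      stop("bin index out of chromosome range")
    flip <- dt$bin_i > dt$bin_j
    if (any(flip)) {
      tmp <- dt$bin_i[flip]
      dt[flip, bin_i := dt$bin_j[flip]]
      dt[flip, bin_j := tmp]
    }
    dt <- dt[, .(count = sum(count)), by = .(chrom, bin_i, bin_j)]
    dt <- dt[count > 0]
  }
  data.table::setkey(dt, chrom, bin_i, bin_j)
  structure(list(genome = genome, triplets = dt,
                 total_valid_pairs = sum(dt$count)),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap: %s triplets, %.0f valid pairs, %d chromosome(s) at %d bp\n",
              format(nrow(x$triplets), big.mark = ","), x$total_valid_pairs,
              length(x$genome$chrom), x$genome$bin_size))
  invisible(x)
}

#' Read a contact-triplet file
#'
#' The portable text format has header lines `#binsize <int>` and one
#' `#chrom <name> <length>` per chromosome, followed by tab-delimited body
#' lines `chrom bin_i bin_j count`.  Transposed duplicates are merged by
#' summation; malformed lines raise an error naming the offending line.
#'
#' @param path file path.
#' @return a [contact_map()].
#' @export
read_contacts <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  if (!length(hdr) || any(diff(hdr) != 1) || hdr[1] != 1)
    stop("contact file must start with a contiguous '#' header block")
  header <- lines[hdr]
  bs_line <- grep("^#binsize\\b", header, value = TRUE)
  if (length(bs_line) != 1) stop("header must contain exactly one '#binsize' line")
  bin_size <- suppressWarnings(as.integer(strsplit(trimws(bs_line), "\\s+")[[1]][2]))
  if (is.na(bin_size) || bin_size <= 0) stop("invalid '#binsize' header")
  ch_lines <- grep("^#chrom\\b", header, value = TRUE)
  if (!length(ch_lines)) stop("header must contain '#chrom <name> <length>' lines")
  ch <- do.call(rbind, strsplit(trimws(ch_lines), "\\s+"))
  genome <- binned_genome(ch[, 2], as.numeric(ch[, 3]), bin_size)

  body_idx <- setdiff(seq_along(lines), hdr)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx]))]
  if (!length(body_idx)) return(contact_map(genome, data.table::data.table(
    chrom = character(), bin_i = integer(), bin_j = integer(), count = numeric())))
  parts <- data.table::tstrsplit(lines[body_idx], "\t", fixed = TRUE)
  if (length(parts) < 4) stop("body lines must have 4 tab-delimited fields")
  dt <- data.table::data.table(
    chrom = parts[[1]],
    bin_i = suppressWarnings(as.integer(parts[[2]])),
    bin_j = suppressWarnings(as.integer(parts[[3]])),
    count = suppressWarnings(as.numeric(parts[[4]])),
    line = body_idx)
  bad <- which(is.na(dt$bin_i) | is.na(dt$bin_j) | is.na(dt$count))
  if (length(bad)) parse_error(path, dt$line[bad[1]], "malformed triplet")
  bad <- which(dt$count < 0)
  if (length(bad)) parse_error(path, dt$line[bad[1]], "negative count")
  bad <- which(!(dt$chrom %in% genome$chrom))
  if (length(bad)) parse_error(path, dt$line[bad[1]],
                               paste0("unknown chromosome '", dt$chrom[bad[1]], "'"))
  nb <- genome$n_bins[dt$chrom]
  bad <- which(dt$bin_i < 0 | dt$bin_j < 0 | dt$bin_i >= nb | dt$bin_j >= nb)
  if (length(bad)) parse_error(path, dt$line[bad[1]], "bin index out of range")
  contact_map(genome, dt[, .(chrom, bin_i, bin_j, count)])
}

parse_error <- function(path, line, msg) {
  stop(structure(class = c("loopscape_parse_error", "error", "condition"),
                 list(message = sprintf("%s:%d: %s", path, line, msg),
                      call = NULL)))
}

#' Write a contact map to the triplet text format
#' @param map a [contact_map()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(map, path) {
  stopifnot(inherits(map, "ContactMap"))
  g <- map$genome
  hdr <- c(sprintf("#binsize %d", g$bin_size),
           sprintf("#chrom %s %.0f", g$chrom, unname(g$length)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (nrow(map$triplets)) {
    dt <- map$triplets[order(chrom, bin_i, bin_j)]
    writeLines(sprintf("%s\t%d\t%d\t%.0f", dt$chrom, dt$bin_i, dt$bin_j, dt$count), con)
  }
  invisible(path)
}

#' Down-sample contact maps to equal valid-pair totals
#'
#' All maps are thinned to the minimum `total_valid_pairs` among them, so
#' samples compared together have an equal number of valid pairs.  Each
#' triplet count is thinned binomially with probability `target / total`,
#' then corrected by +/-1 adjustments on randomly chosen nonzero triplets so
#' the target is hit exactly.  The minimum-depth map is returned unchanged.
#'
#' @param maps a list of two or more [contact_map()] objects over the same
#'   genome.
#' @param seed integer seed; the operation is deterministic given
#'   `(maps, seed)`.
#' @return a list of [contact_map()] objects with identical totals.
#' @export
downsample <- function(maps, seed = 1L) {
  stopifnot(is.list(maps), length(maps) >= 2,
            all(vapply(maps, inherits, logical(1), "ContactMap")))
  if (any(vapply(maps, function(m) nrow(m$triplets) == 0, logical(1))))
    stop("cannot downsample an empty contact map")
  for (m in maps[-1]) if (!same_genome(maps[[1]]$genome, m$genome))
    stop("maps must share one BinnedGenome")
  totals <- vapply(maps, function(m) m$total_valid_pairs, numeric(1))
  target <- min(totals)
  set.seed(as.integer(seed))
  out <- lapply(maps, downsample_one, target = target)
  names(out) <- names(maps)
  out
}

# thin one map to `target` valid pairs using the current RNG state; the
# caller controls seeding so maps can be processed (and released) one at a
# time without changing the random stream of downsample()
downsample_one <- function(m, target) {
  if (m$total_valid_pairs == target) return(m)
  dt <- data.table::copy(m$triplets)
  orig <- dt$count
  dt[, count := stats::rbinom(.N, size = as.integer(orig), prob = target / m$total_valid_pairs)]
  diff <- target - sum(dt$count)
  while (diff != 0) {
    if (diff > 0) {
      # room to add: triplets thinned below their original count
      idx <- which(dt$count < orig)
      pick <- idx[sample.int(length(idx), min(diff, length(idx)))]
      dt[pick, count := count + 1]
    } else {
      idx <- which(dt$count > 0)
      pick <- idx[sample.int(length(idx), min(-diff, length(idx)))]
      dt[pick, count := count - 1]
    }
    diff <- target - sum(dt$count)
  }
  contact_map(m$genome, dt)
}

#' ICE matrix balancing
#'
#' Iterative correction: per chromosome, bin weights `w` are repeatedly
#' divided by the weighted marginal (rescaled to unit mean each pass) until
#' the maximum relative marginal deviation falls below `tol` or `max_iter`
#' is reached.  The balanced value is `B(i, j) = w_i * w_j * count(i, j)`;
#' on convergence all non-missing marginals of `B` agree within `tol`.
#' Bins with zero raw marginal get a missing (`NA`) weight.
#'
#' @param map a [contact_map()].
#' @param max_iter maximum iterations (default 200).
#' @param tol relative marginal tolerance (default 1e-5).
#' @return An object of class `BalanceWeights`: a `data.table` with columns
#'   `chrom`, `bin`, `weight` (NA = missing), plus attribute `converged`
#'   (named logical per chromosome).  Non-convergence is flagged, not an
#'   error.
#' @export
ice_balance <- function(map, max_iter = 200, tol = 1e-5) {
  stopifnot(inherits(map, "ContactMap"))
  if (nrow(map$triplets) == 0) stop("cannot balance an empty contact map")
  g <- map$genome
  out <- vector("list", length(g$chrom))
  conv <- logical(length(g$chrom))
  names(conv) <- g$chrom
  for (ci in seq_along(g$chrom)) {
    cn <- g$chrom[ci]
    n <- g$n_bins[[cn]]
    A <- chrom_sparse(map, cn)
    w <- rep(1, n)
    marg0 <- as.numeric(A %*% rep(1, n))
    miss <- marg0 == 0
    w[miss] <- NA_real_
    ok <- FALSE
    if (all(miss)) {
      conv[ci] <- TRUE
    } else {
      for (it in seq_len(max_iter)) {
        wv <- ifelse(is.na(w), 0, w)
        m <- wv * as.numeric(A %*% wv)
        mb <- mean(m[!miss])
        dev <- max(abs(m[!miss] / mb - 1))
        if (dev < tol) { ok <- TRUE; break }
        w[!miss] <- w[!miss] / (m[!miss] / mb)
      }
      conv[ci] <- ok
    }
    out[[ci]] <- data.table::data.table(chrom = cn, bin = 0:(n - 1L), weight = w)
  }
  res <- data.table::rbindlist(out)
  data.table::setkey(res, chrom, bin)
  structure(res, class = c("BalanceWeights", class(res)), converged = conv)
}

# symmetric sparse matrix of one chromosome (1-based dgCMatrix)
chrom_sparse <- function(map, chrom, weights = NULL) {
  n <- map$genome$n_bins[[chrom]]
  dt <- map$triplets[chrom, on = "chrom", nomatch = NULL]
  if (nrow(dt) == 0)
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n), symmetric = TRUE))
  x <- dt$count
  if (!is.null(weights)) {
    wv <- weight_vector(weights, chrom, n)
    x <- x * wv[dt$bin_i + 1L] * wv[dt$bin_j + 1L]
  }
  Matrix::sparseMatrix(i = dt$bin_i + 1L, j = dt$bin_j + 1L, x = x,
                       dims = c(n, n), symmetric = TRUE)
}

weight_vector <- function(weights, chrom, n) {
  wdt <- weights[chrom, on = "chrom", nomatch = NULL]
  wv <- rep(NA_real_, n)
  wv[wdt$bin + 1L] <- wdt$weight
  wv
}

#' Expected contacts by genomic distance
#'
#' The distance-decay expected model: `E(d)` is the mean count over all
#' valid bin pairs at separation `d` (zero-count pairs included in the
#' denominator).  With balance weights, balanced values are averaged and
#' pairs touching a missing bin are excluded.  Strata pooled across
#' chromosomes.  Distances with no valid pairs are absent, not 0/0.
#'
#' @param map a [contact_map()].
#' @param weights optional [ice_balance()] result.
#' @return An object of class `DecayProfile`: `data.table` with columns `d`,
#'   `expected`, `n_pairs`; attribute `balanced`.
#' @export
expected_by_distance <- function(map, weights = NULL) {
  stopifnot(inherits(map, "ContactMap"))
  if (nrow(map$triplets) == 0) stop("empty contact map")
  g <- map$genome
  maxn <- max(g$n_bins)
  sums <- numeric(maxn)          # indexed by d + 1
  npairs <- numeric(maxn)
  for (cn in g$chrom) {
    n <- g$n_bins[[cn]]
    dt <- map$triplets[cn, on = "chrom", nomatch = NULL]
    if (is.null(weights)) {
      npairs[1:n] <- npairs[1:n] + (n - 0:(n - 1L))
      if (nrow(dt)) {
        d <- dt$bin_j - dt$bin_i
        agg <- rowsum(dt$count, d)
        sums[as.integer(rownames(agg)) + 1L] <- sums[as.integer(rownames(agg)) + 1L] + agg[, 1]
      }
    } else {
      wv <- weight_vector(weights, cn, n)
      present <- !is.na(wv)
      # n_d = pairs with both bins non-missing at distance d
      if (all(present)) {
        npairs[1:n] <- npairs[1:n] + (n - 0:(n - 1L))
      } else {
        for (d in 0:(n - 1L)) {
          a <- 1:(n - d)
          npairs[d + 1L] <- npairs[d + 1L] + sum(present[a] & present[a + d])
        }
      }
      if (nrow(dt)) {
        val <- dt$count * wv[dt$bin_i + 1L] * wv[dt$bin_j + 1L]
        keep <- !is.na(val)
        if (any(keep)) {
          d <- (dt$bin_j - dt$bin_i)[keep]
          agg <- rowsum(val[keep], d)
          sums[as.integer(rownames(agg)) + 1L] <- sums[as.integer(rownames(agg)) + 1L] + agg[, 1]
        }
      }
    }
  }
  keep <- npairs > 0
  res <- data.table::data.table(d = which(keep) - 1L,
                                expected = sums[keep] / npairs[keep],
                                n_pairs = npairs[keep])
  data.table::setkey(res, d)
  structure(res, class = c("DecayProfile", class(res)),
            balanced = !is.null(weights))
}
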