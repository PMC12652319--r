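test_that("oe_matrix is ~1 on a flat map and NA off the valid band", {
  m <- flat_map(n = 40L)
  pr <- expected_by_distance(m)
  OE <- loopscape:::oe_matrix(m, "chrF", NULL, pr)
  expect_equal(dim(OE), c(40L, 40L))
  off <- OE[row(OE) != col(OE)]
  expect_true(all(abs(off - 1) < 1e-12))
  # d = 0 stratum has zero expected -> undefined
  expect_true(all(is.na(diag(OE))))
})

test_that("oe_matrix refuses a profile whose balance state mismatches", {
  m <- flat_map(n = 20L)
  w <- ice_balance(m)
  pr_raw <- expected_by_distance(m)
  expect_error(loopscape:::oe_matrix(m, "chrF", w, pr_raw),
               "balancing state")
})

test_that("APA recovers the planted center enrichment on a flat map", {
  hot <- data.frame(bin_i = c(40L, 100L), bin_j = c(80L, 150L),
                    count = c(24L, 24L))
  m <- flat_map(n = 200L, base = 4L, hot = hot)
  pr <- expected_by_distance(m)
  loops <- data.table::data.table(chrom = "chrF", bin_i = hot$bin_i,
                                  bin_j = hot$bin_j)
  res <- apa(m, NULL, pr, loops, w = 10L, corner = 6L)
  expect_s3_class(res, "ApaResult")
  expect_equal(res$n_used, 2L)
  expect_equal(dim(res$aggregate), c(21L, 21L))
  # center O/E ~6 (the hot pixel leaks slightly into its own stratum's
  # expectation), corner O/E ~1 -> score just under 6
  expect_gt(res$score, 5.5)
  expect_lt(res$score, 6.05)
})

test_that("APA skips near-diagonal and out-of-range loops", {
  m <- flat_map(n = 60L)
  pr <- expected_by_distance(m)
  loops <- data.table::data.table(
    chrom = "chrF",
    bin_i = c(12L, 5L, 30L),
    bin_j = c(45L, 20L, 55L))   # d = 15 <= 2w skipped; j + w > n - 1 skipped
  res <- apa(m, NULL, pr, loops, w = 10L)
  expect_equal(res$n_used, 1L)
  expect_equal(res$n_skipped, 2L)
  expect_error(apa(m, NULL, pr, loops[2], w = 10L), "no usable loops")
})

test_that("pixel_enrichment excludes the center block from its background", {
  hot <- data.frame(bin_i = 40L, bin_j = 80L, count = 40L)
  m <- flat_map(n = 150L, base = 4L, hot = hot)
  pr <- expected_by_distance(m)
  loops <- data.table::data.table(chrom = "chrF", bin_i = 40L, bin_j = 80L)
  fe <- pixel_enrichment(m, NULL, pr, loops, w = 5L, exclusion = 1L)
  # exact oracle: the hot pixel inflates E(40); the 11x11 window holds 8
  # non-excluded cells of stratum 40 (O/E 4 / E40) and 104 cells of O/E 1
  E40 <- (4 * 109 + 40) / 110
  fe_exp <- (40 / E40) / ((104 + 8 * (4 / E40)) / 112)
  expect_equal(unname(as.numeric(fe)), fe_exp, tolerance = 1e-9)
  # near-diagonal loop -> NA (flagged marks undefined backgrounds only)
  fe2 <- pixel_enrichment(m, NULL, pr,
                          data.table::data.table(chrom = "chrF", bin_i = 10L,
                                                 bin_j = 12L), w = 5L)
  expect_true(is.na(fe2))
  expect_false(attr(fe2, "flagged"))
})

test_that("summed-area tables match naive window sums", {
  set.seed(3)
  M <- matrix(rnorm(15 * 15), 15, 15)
  M[sample(225, 20)] <- NA
  S <- loopscape:::sat(M)
  naive <- function(r1, r2, c1, c2) {
    v <- M[r1:r2, c1:c2]
    c(sum(v, na.rm = TRUE), sum(!is.na(v)))
  }
  for (q in list(c(1, 5, 2, 7), c(3, 10, 3, 10), c(8, 15, 1, 15))) {
    got <- c(loopscape:::sat_query(S$sum, q[1], q[2], q[3], q[4]),
             loopscape:::sat_query(S$cnt, q[1], q[2], q[3], q[4]))
    expect_equal(got, naive(q[1], q[2], q[3], q[4]))
  }
})

test_that("smooth_matrix equals the naive truncated mean filter", {
  set.seed(4)
  M <- matrix(rpois(100, 5), 10, 10)
  Sm <- loopscape:::smooth_matrix(M, 1L)
  naive <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10) {
    ri <- max(1, i - 1):min(10, i + 1)
    rj <- max(1, j - 1):min(10, j + 1)
    naive[i, j] <- mean(M[ri, rj])
  }
  expect_equal(Sm, naive)
  expect_equal(loopscape:::smooth_matrix(M, 0L), M)
})

test_that("insulation computes diamond means and flags prominent minima", {
  # two dense blocks [0, 20) and [20, 40) with weak inter-block contact
  n <- 40L
  g <- binned_genome("chrI", n * 5000, 5000)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1] - 1L; j <- ij[, 2] - 1L
  cnt <- ifelse((i < 20L) == (j < 20L), 20L, 1L)
  m <- contact_map(g, data.table::data.table(chrom = "chrI", bin_i = i,
                                             bin_j = j, count = cnt))
  tr <- insulation(m, window = 5L, min_prominence = 0.1)
  expect_s3_class(tr, "InsulationTrack")
  # raw at the boundary bin 20: diamond rows 16..20, cols 21..25 (1-based)
  # all cross-block -> mean 1
  expect_equal(tr[tr$chrom == "chrI" & tr$bin == 19L, ]$raw, 1)
  # deep interior diamond is all intra-block -> mean 20
  expect_equal(tr[tr$bin == 10L, ]$raw, 20)
  b <- boundaries(tr)
  expect_equal(nrow(b), 1L)
  expect_true(abs(b$bin - 19L) <= 1L)
})

test_that("prominence is the topographic walk-out height of minima", {
  x <- c(0, -1, 0.5, -0.2, 0.3)
  prom <- loopscape:::prominence_of_minima(x)
  expect_equal(prom[2], 1)     # min(max left 0, max right 0.5) - (-1)
  expect_equal(prom[4], 0.5)   # min(0.5, 0.3) - (-0.2)
  expect_true(all(is.na(prom[c(1, 3, 5)])))
})

test_that("SCC is 1 for proportional replicates and sensitive to noise", {
  m <- fixture("scc_structured_map", function() {
    set.seed(9)
    n <- 120L
    g <- binned_genome("chrS", n * 5000, 5000)
    ij <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
    i <- ij[, 1] - 1L; j <- ij[, 2] - 1L
    lam <- 50 / (1 + (j - i)) * (1 + 0.5 * sin(i / 7) * sin(j / 7))
    contact_map(g, data.table::data.table(chrom = "chrS", bin_i = i,
                                          bin_j = j,
                                          count = rpois(length(i), lam)))
  })
  m2 <- contact_map(m$genome, data.table::copy(m$triplets)[, count := count * 2])
  res <- scc(m, m2, h = 1L, max_dist_bins = 100L)
  expect_s3_class(res, "SccResult")
  expect_equal(unname(res$scc[["chrS"]]), 1, tolerance = 1e-12)
  # shuffled counts destroy the correlation
  set.seed(10)
  tr <- data.table::copy(m$triplets)[, count := sample(count)]
  m3 <- contact_map(m$genome, tr)
  res2 <- scc(m, m3, h = 1L, max_dist_bins = 100L)
  expect_lt(res2$scc[["chrS"]], 0.9)
  # per-stratum weights are N_k * s_x * s_y
  st <- res$strata[!is.na(rho)]
  expect_equal(unname(res$scc[["chrS"]]),
               sum(st$n * st$s_x * st$s_y * st$rho) /
                 sum(st$n * st$s_x * st$s_y))
})

test_that("scc validates genome compatibility", {
  a <- flat_map(n = 30L)
  b <- flat_map(n = 31L)
  expect_error(scc(a, b), "share one BinnedGenome")
})

test_that("leading_eigenvector matches eigen() on a PSD matrix", {
  set.seed(5)
  X <- matrix(rnorm(30 * 8), 30, 8)
  C <- crossprod(X) / 30
  v <- loopscape:::leading_eigenvector(C)
  ref <- eigen(C, symmetric = TRUE)$vectors[, 1]
  if (sum(v * ref) < 0) ref <- -ref
  expect_equal(v, ref, tolerance = 1e-4)
  # residual check: v is an eigenvector of C
  lam <- as.numeric(crossprod(v, C %*% v))
  expect_lt(sqrt(sum((as.numeric(C %*% v) - lam * v)^2)), 1e-4)
})

test_that("compartment_eigenvector recovers a planted checkerboard", {
  n <- 80L
  g <- binned_genome("chrC", n * 5000, 5000)
  s <- rep(c(1, -1), each = 20L, times = 2L)   # A/B blocks of 20 bins
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- ij[, 1] - 1L; j <- ij[, 2] - 1L
  lam <- 40 / (1 + (j - i)) * (1 + 0.4 * s[i + 1] * s[j + 1])
  set.seed(6)
  m <- contact_map(g, data.table::data.table(chrom = "chrC", bin_i = i,
                                             bin_j = j,
                                             count = rpois(length(i), lam)))
  pr <- expected_by_distance(m)
  ref <- data.table::data.table(chrom = "chrC", bin = 0:(n - 1L), value = s)
  ev <- compartment_eigenvector(m, NULL, pr, ref)
  expect_s3_class(ev, "CompartmentTrack")
  acc <- mean(ev$label == ifelse(s > 0, "A", "B"), na.rm = TRUE)
  expect_gt(acc, 0.95)
  # flipping the reference flips the sign convention
  ref2 <- data.table::copy(ref)[, value := -value]
  ev2 <- compartment_eigenvector(m, NULL, pr, ref2)
  ok <- !is.na(ev$value) & !is.na(ev2$value)
  expect_equal(ev2$value[ok], -ev$value[ok])
})

test_that("profile_at_sites averages a track around site centers", {
  g <- binned_genome("chr1", 1e5, 5000)
  tr <- data.table::data.table(chrom = "chr1", bin = 0:19,
                               score = as.numeric(0:19))
  sites <- data.table::data.table(chrom = "chr1", start = 50000, end = 55000)
  out <- profile_at_sites(tr, sites, flank_bins = 2L, genome = g)
  expect_equal(out$offset, -2:2)
  expect_equal(out$mean_value, c(8, 9, 10, 11, 12))
  expect_equal(out$n, rep(1L, 5))
})
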