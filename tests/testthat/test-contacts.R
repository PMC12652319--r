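make_genome1 <- function(n = 10L) binned_genome("chr1", n * 5000, 5000)

test_that("contact_map merges transposed duplicates into the upper triangle", {
  g <- make_genome1()
  m <- contact_map(g, data.frame(chrom = "chr1", bin_i = c(2L, 5L),
                                 bin_j = c(5L, 2L), count = c(3, 4)))
  expect_equal(nrow(m$triplets), 1L)
  expect_equal(m$triplets$bin_i, 2L)
  expect_equal(m$triplets$bin_j, 5L)
  expect_equal(m$triplets$count, 7)
  expect_equal(m$total_valid_pairs, 7)
})

test_that("contact_map validates counts and bin ranges", {
  g <- make_genome1()
  tri <- function(i, j, k) data.frame(chrom = "chr1", bin_i = i, bin_j = j,
                                      count = k)
  expect_error(contact_map(g, tri(0L, 1L, -1)), "negative")
  expect_error(contact_map(g, tri(0L, 1L, 1.5)), "non-integer")
  expect_error(contact_map(g, tri(0L, 10L, 1)), "out of chromosome range")
  expect_error(contact_map(g, data.frame(chrom = "chrX", bin_i = 0L,
                                         bin_j = 1L, count = 1)),
               "unknown chromosome")
})

test_that("contact files round-trip through the triplet text format", {
  g <- binned_genome(c("chr1", "chr2"), c(50000, 30000), 5000)
  m <- contact_map(g, data.frame(
    chrom = c("chr1", "chr1", "chr2"), bin_i = c(0L, 3L, 1L),
    bin_j = c(4L, 3L, 5L), count = c(2, 7, 1)))
  path <- tempfile(fileext = ".txt")
  write_contacts(m, path)
  m2 <- read_contacts(path)
  expect_true(loopscape:::same_genome(m$genome, m2$genome))
  expect_equal(as.data.frame(m2$triplets), as.data.frame(m$triplets))
  expect_equal(m2$total_valid_pairs, 10)
})

test_that("read_contacts raises typed parse errors naming the line", {
  path <- tempfile()
  writeLines(c("#binsize 5000", "#chrom chr1 50000",
               "chr1\t0\t1\ttwo"), path)
  err <- tryCatch(read_contacts(path), error = identity)
  expect_s3_class(err, "loopscape_parse_error")
  expect_match(conditionMessage(err), ":3: malformed triplet")

  writeLines(c("#binsize 5000", "#chrom chr1 50000",
               "chrZ\t0\t1\t5"), path)
  expect_error(read_contacts(path), "unknown chromosome 'chrZ'",
               class = "loopscape_parse_error")

  writeLines(c("#binsize 5000", "#chrom chr1 50000",
               "chr1\t0\t99\t5"), path)
  expect_error(read_contacts(path), "out of range",
               class = "loopscape_parse_error")

  writeLines(c("#chrom chr1 50000", "chr1\t0\t1\t5"), path)
  expect_error(read_contacts(path), "#binsize")
})

test_that("downsample equalizes totals exactly and keeps the floor map", {
  g <- make_genome1(20L)
  set.seed(42)
  mk <- function(total) {
    ij <- which(upper.tri(matrix(0, 20, 20)), arr.ind = TRUE)
    cnt <- as.vector(stats::rmultinom(1, total, rep(1, nrow(ij))))
    contact_map(g, data.frame(chrom = "chr1", bin_i = ij[, 1] - 1L,
                              bin_j = ij[, 2] - 1L, count = cnt))
  }
  a <- mk(2000); b <- mk(1000)
  out <- downsample(list(a, b), seed = 5L)
  expect_equal(out[[1]]$total_valid_pairs, 1000)
  expect_identical(out[[2]]$triplets, b$triplets)  # min map unchanged
  # deterministic given (maps, seed)
  out2 <- downsample(list(a, b), seed = 5L)
  expect_identical(out[[1]]$triplets, out2[[1]]$triplets)
  # equal totals: returned unchanged
  same <- downsample(list(b, b), seed = 1L)
  expect_identical(same[[1]]$triplets, b$triplets)
  expect_error(downsample(list(a)), "length")
  # list names survive
  named <- downsample(list(WT = a, mut = b), seed = 5L)
  expect_equal(names(named), c("WT", "mut"))
})

test_that("binomial thinning preserves expectation (200 seeds, 3 SE)", {
  g <- make_genome1(4L)
  a <- contact_map(g, data.frame(chrom = "chr1", bin_i = c(0L, 1L),
                                 bin_j = c(2L, 3L), count = c(300, 100)))
  b <- contact_map(g, data.frame(chrom = "chr1", bin_i = 0L, bin_j = 1L,
                                 count = 200))
  vals <- vapply(1:200, function(s) {
    out <- downsample(list(a, b), seed = s)[[1]]
    out$triplets[bin_i == 0L & bin_j == 2L, count]
  }, numeric(1))
  expected <- 300 * 200 / 400
  se <- sqrt(300 * 0.5 * 0.5) / sqrt(200)
  expect_lt(abs(mean(vals) - expected), 3 * se)
})

test_that("ICE balancing equalizes marginals within tolerance", {
  g <- make_genome1(6L)
  set.seed(1)
  ij <- which(upper.tri(matrix(0, 6, 6)), arr.ind = TRUE)
  m <- contact_map(g, data.frame(chrom = "chr1", bin_i = ij[, 1] - 1L,
                                 bin_j = ij[, 2] - 1L,
                                 count = sample(1:50, nrow(ij), replace = TRUE)))
  w <- ice_balance(m, tol = 1e-8)
  expect_s3_class(w, "BalanceWeights")
  expect_true(attr(w, "converged")[["chr1"]])
  B <- as.matrix(loopscape:::chrom_sparse(m, "chr1", w))
  marg <- rowSums(B)
  expect_lt(max(abs(marg / mean(marg) - 1)), 1e-7)
})

test_that("ICE flags zero-marginal bins NA and is idempotent when balanced", {
  g <- make_genome1(5L)
  m <- contact_map(g, data.frame(chrom = "chr1",
                                 bin_i = c(0L, 0L, 1L, 2L),
                                 bin_j = c(1L, 2L, 2L, 3L),
                                 count = c(5, 3, 2, 4)))
  w <- ice_balance(m)
  expect_true(is.na(w[chrom == "chr1" & bin == 4L, weight]))
  # circulant-style matrix with equal marginals is already balanced:
  # one pass leaves all weights equal
  mb <- contact_map(g, data.frame(
    chrom = "chr1",
    bin_i = c(0L, 1L, 2L, 3L, 0L, 1L, 2L, 0L, 1L, 0L),
    bin_j = c(1L, 2L, 3L, 4L, 2L, 3L, 4L, 3L, 4L, 4L),
    count = c(4L, 4L, 4L, 4L, 3L, 3L, 3L, 3L, 3L, 4L)))
  wb <- ice_balance(mb, tol = 1e-6)
  expect_true(attr(wb, "converged")[["chr1"]])
  expect_lt(diff(range(wb$weight)), 1e-6)
})

test_that("expected_by_distance averages over all pairs, zeros included", {
  g <- make_genome1(4L)
  m <- contact_map(g, data.frame(chrom = "chr1", bin_i = c(0L, 1L, 0L),
                                 bin_j = c(1L, 2L, 2L), count = c(6, 3, 4)))
  pr <- expected_by_distance(m)
  expect_s3_class(pr, "DecayProfile")
  expect_false(attr(pr, "balanced"))
  # d = 1: pairs (0,1), (1,2), (2,3) -> (6 + 3 + 0) / 3
  expect_equal(pr[pr$d == 1, ]$expected, 3)
  expect_equal(pr[pr$d == 1, ]$n_pairs, 3)
  # d = 2: pairs (0,2), (1,3) -> (4 + 0) / 2
  expect_equal(pr[pr$d == 2, ]$expected, 2)
  # d = 0 band has pairs but zero counts
  expect_equal(pr[pr$d == 0, ]$expected, 0)
})

test_that("balanced expected excludes pairs touching missing bins", {
  g <- make_genome1(4L)
  m <- contact_map(g, data.frame(chrom = "chr1", bin_i = c(0L, 1L, 0L),
                                 bin_j = c(1L, 2L, 2L), count = c(6, 3, 4)))
  w <- ice_balance(m)   # bin 3 has zero marginal -> NA weight
  pr <- expected_by_distance(m, w)
  expect_true(attr(pr, "balanced"))
  expect_equal(pr[pr$d == 1, ]$n_pairs, 2)  # (2,3) dropped
  expect_equal(pr[pr$d == 2, ]$n_pairs, 1)  # (1,3) dropped
  wv <- loopscape:::weight_vector(w, "chr1", 4L)
  expect_equal(pr[pr$d == 1, ]$expected,
               (6 * wv[1] * wv[2] + 3 * wv[2] * wv[3]) / 2)
})
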