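clip_genome <- function(len = 100000) binned_genome("chrX", len, 5000)

test_that("crosslink sites sit one nt 5' of the read 5' end", {
  g <- clip_genome()
  al <- data.table::data.table(
    chrom = "chrX",
    start = c(100L, 0L, 500L, 600L),
    end = c(130L, 30L, 530L, 100000L),
    strand = c("+", "+", "-", "-"))
  tr <- extract_crosslink_sites(al, g)
  dt <- data.table::as.data.table(tr)
  # plus read [100,130) -> 99; plus read at 0 -> dropped (pos -1)
  # minus read [500,530) -> 530; minus read ending at the chrom end -> dropped
  expect_equal(dt[strand == "+", pos], 99L)
  expect_equal(dt[strand == "-", pos], 530L)
  expect_equal(attr(tr, "n_dropped"), 2L)
  expect_error(extract_crosslink_sites(
    data.table::data.table(chrom = "chrX", start = 1L, end = 2L,
                           strand = "*"), g), "strand")
})

test_that("crosslink_track aggregates duplicate events and validates", {
  g <- clip_genome()
  ev <- data.table::data.table(chrom = "chrX", pos = c(10L, 10L, 20L),
                               strand = c("+", "+", "-"), count = c(1L, 2L, 5L))
  tr <- crosslink_track(ev, g, replicate = 2L, condition = "NPC")
  dt <- data.table::as.data.table(tr)
  expect_equal(dt[pos == 10L, count], 3L)
  expect_equal(attr(tr, "replicate"), 2L)
  expect_false(attr(tr, "is_control"))
  expect_error(crosslink_track(
    data.table::data.table(chrom = "chrX", pos = -1L, strand = "+",
                           count = 1L), g), "position")
  expect_error(crosslink_track(
    data.table::data.table(chrom = "chrX", pos = 1L, strand = "+",
                           count = 0L), g), "positive")
})

test_that("merge_tracks sums counts across replicates", {
  g <- clip_genome()
  mk <- function(pos, count, r) crosslink_track(
    data.table::data.table(chrom = "chrX", pos = pos, strand = "+",
                           count = count), g, replicate = r)
  merged <- merge_tracks(list(mk(10L, 2L, 1), mk(c(10L, 40L), c(3L, 1L), 2)))
  dt <- data.table::as.data.table(merged)
  expect_equal(dt$pos, c(10L, 40L))
  expect_equal(dt$count, c(5L, 1L))
  expect_equal(attr(merged, "replicate"), "merged")
})

test_that("window_sums matches a naive windowed sum", {
  pos <- sort(sample(0:999, 60))
  cnt <- sample(1:5, 60, replace = TRUE)
  centers <- c(0L, 100L, 500L, 999L)
  got <- loopscape:::window_sums(pos, cnt, centers, 50L)
  naive <- vapply(centers, function(ce)
    sum(cnt[pos >= ce - 50 & pos <= ce + 50]), numeric(1))
  expect_equal(got, naive)
})

test_that("candidate peaks cluster significant sites by the gap rule", {
  g <- clip_genome()
  # a sparse background plus two hot clusters on the plus strand
  set.seed(30)
  bg <- data.table::data.table(chrom = "chrX",
                               pos = sample(0:99999, 400),
                               strand = sample(c("+", "-"), 400, TRUE),
                               count = 1L)
  hot <- data.table::data.table(
    chrom = "chrX",
    pos = c(5000L, 5010L, 5015L,      # one cluster (gaps <= 15)
            9000L, 9016L),            # two clusters (gap 16 > 15)
    strand = "+",
    count = c(30L, 40L, 40L, 25L, 25L))
  tr <- crosslink_track(rbind(bg, hot), g)
  summits <- call_candidate_peaks(tr, bg_window = 2001L, alpha = 0.01,
                                  gap = 15L)
  got <- summits[summits$strand == "+" & summits$count >= 25L]
  expect_equal(nrow(got), 3L)
  # summit = leftmost maximum of the cluster (counts 40, 40 tie -> 5010)
  expect_equal(sort(got$pos), c(5010L, 9000L, 9016L))
  c1 <- got[got$pos == 5010L]
  expect_equal(c(c1$cluster_start, c1$cluster_end), c(5000L, 5016L))
})

test_that("standardize_peaks builds clipped fixed-width windows greedily", {
  g <- clip_genome()
  summits <- data.table::data.table(
    chrom = "chrX", pos = c(60L, 5000L, 5100L, 99990L),
    strand = "+", count = c(9L, 10L, 6L, 3L),
    q_value = 1e-6, cluster_start = c(60L, 5000L, 5100L, 99990L),
    cluster_end = c(61L, 5001L, 5101L, 99991L))
  pk <- standardize_peaks(summits, g, width = 300L)
  expect_s3_class(pk, "ClipPeakSet")
  # summit 5100 (count 6) overlaps the kept 5000 window -> discarded
  expect_equal(attr(pk, "n_discarded"), 1L)
  expect_false(5100L %in% pk$summit)
  # clipping at chromosome boundaries
  expect_equal(pk[pk$summit == 60L, ]$start, 0L)
  expect_equal(pk[pk$summit == 99990L, ]$end, 100000L)
  expect_equal(pk[pk$summit == 5000L, ]$start, 4850L)
  expect_equal(pk[pk$summit == 5000L, ]$end, 5150L)
})

test_that("peak_event_counts sums strand-matched events in [start, end)", {
  g <- clip_genome()
  tr <- crosslink_track(data.table::data.table(
    chrom = "chrX", pos = c(100L, 150L, 199L, 200L, 120L),
    strand = c("+", "+", "+", "+", "-"), count = c(2L, 3L, 1L, 7L, 9L)), g)
  pk <- data.table::data.table(chrom = "chrX", start = 100L, end = 200L,
                               strand = "+")
  expect_equal(peak_event_counts(pk, tr), 6L)   # 200 excluded, minus ignored
})

test_that("reproducibility needs the percentile cutoff in >= 3 of 4 reps", {
  g <- clip_genome()
  # 10 candidate peaks at distinct positions
  pk_pos <- seq(1000L, 91000L, by = 10000L)
  summits <- data.table::data.table(
    chrom = "chrX", pos = pk_pos, strand = "+", count = 20L,
    q_value = 1e-6, cluster_start = pk_pos, cluster_end = pk_pos + 1L)
  pk <- standardize_peaks(summits, g, width = 300L)
  # replicate r supports peaks 1..(10 - r + 1): peak 1 in all 4, peak 8 in 3,
  # peak 10 in 1
  mk_rep <- function(r) crosslink_track(data.table::data.table(
    chrom = "chrX", pos = pk_pos[seq_len(11L - r) - 0L], strand = "+",
    count = 5L), g, replicate = r)
  reps <- lapply(1:4, mk_rep)
  out <- reproducibility_filter(pk, reps, percentile = 10, min_required = 3L)
  expect_true(all(c("rep_1", "rep_2", "rep_3", "rep_4") %in% names(out)))
  # counts are 0 or 5; every cutoff floors at max(1, quantile)
  expect_true(all(attr(out, "cutoffs") >= 1))
  ord <- order(out$summit)
  expect_equal(out$n_reproducing[ord], c(rep(4, 7), 3, 2, 1))
  expect_equal(out$reproducible[ord], c(rep(TRUE, 8), FALSE, FALSE))
  expect_error(reproducibility_filter(pk, reps, percentile = 0), "percentile")
  expect_error(reproducibility_filter(pk, reps, min_required = 5L),
               "min_required")
})

test_that("control filter removes >= 20% coverage, boundary inclusive", {
  g <- clip_genome()
  pk <- data.table::data.table(
    chrom = "chrX", start = c(1000L, 5000L, 9000L), end = c(1300L, 5300L, 9300L),
    strand = "+", summit = c(1150L, 5150L, 9150L), summit_count = 10L,
    name = c("p1", "p2", "p3"))
  pk <- structure(pk, class = c("ClipPeakSet", class(pk)), genome = g)
  ctl <- data.table::data.table(
    chrom = "chrX",
    start = c(1000L, 5000L),
    end = c(1060L, 5059L),     # 60 bp = exactly 20%; 59 bp = 19.7%
    strand = "+")
  out <- control_filter(pk, ctl, max_overlap_fraction = 0.20)
  expect_equal(sort(out$name), c("p2", "p3"))
  expect_equal(attr(out, "n_removed"), 1L)
  expect_equal(out[out$name == "p2", ]$control_overlap_fraction, 59 / 300)
  # strand-mismatched control peaks do not count
  ctl_minus <- data.table::copy(ctl)[, strand := "-"]
  out2 <- control_filter(pk, ctl_minus)
  expect_equal(nrow(out2), 3L)
})

test_that("peaks are assigned to the strand-matched gene at their midpoint", {
  genes <- data.table::data.table(
    id = c("gA", "gB", "gC"), chrom = "chrX",
    strand = c("+", "+", "-"),
    tss = c(1000L, 1400L, 3000L), tes = c(2000L, 2400L, 2500L))
  pk <- data.table::data.table(chrom = "chrX", start = c(1350L, 2600L, 100L),
                               end = c(1650L, 2900L, 400L),
                               strand = c("+", "-", "+"))
  out <- assign_genes(pk, genes)
  # midpoint 1500 inside gA [1000,2000) and gB [1400,2400); overlap with gA
  # is [1350,1650) = 300, with gB [1400,1650) = 250 -> gA
  expect_equal(out$gene_id, c("gA", "gC", NA))
  expect_equal(out$intergenic, c(FALSE, FALSE, TRUE))
})

test_that("gene tie at equal overlap breaks lexicographically", {
  genes <- data.table::data.table(
    id = c("gB", "gA"), chrom = "chrX", strand = "+",
    tss = c(1000L, 1000L), tes = c(2000L, 2000L))
  pk <- data.table::data.table(chrom = "chrX", start = 1350L, end = 1650L,
                               strand = "+")
  expect_equal(assign_genes(pk, genes)$gene_id, "gA")
})

test_that("clip_gene_counts totals strand-matched body events", {
  g <- clip_genome()
  genes <- data.table::data.table(id = "gA", chrom = "chrX", strand = "+",
                                  tss = 1000L, tes = 2000L)
  tr <- crosslink_track(data.table::data.table(
    chrom = "chrX", pos = c(1000L, 1999L, 2000L, 1500L),
    strand = c("+", "+", "+", "-"), count = c(1L, 2L, 4L, 8L)), g)
  cnt <- clip_gene_counts(genes, list(s1 = tr))
  expect_equal(unname(cnt[1, 1]), 3L)
})

test_that("crosslink tracks round-trip through bedGraph pairs", {
  g <- clip_genome()
  tr <- crosslink_track(data.table::data.table(
    chrom = "chrX", pos = c(5L, 10L, 20L), strand = c("+", "-", "+"),
    count = c(2L, 1L, 4L)), g, replicate = 3L, condition = "NPC")
  prefix <- tempfile()
  write_crosslink_track(tr, prefix)
  back <- read_crosslink_track(prefix, g, replicate = 3L, condition = "NPC")
  expect_equal(as.data.frame(back), as.data.frame(tr))
})

test_that("the end-to-end CLIP pipeline returns consistent components", {
  cfg <- mid_cfg()
  truth <- mid_truth()
  sim <- simulate_clip(cfg, cell = "NPC", seed = 77L, truth = truth)
  out <- clip_peaks(sim$replicates, sim$control, genes = truth$genes,
                    bg_window = 5001L)
  expect_true(nrow(out$peaks) > 0)
  expect_true(all(out$peaks$reproducible))
  expect_true(all(out$peaks$control_overlap_fraction < 0.20))
  expect_equal(length(out$cutoffs), length(sim$replicates))
  expect_true(all(out$peaks$end - out$peaks$start <= 300L))
  # peaks fall overwhelmingly in CLIP-positive gene bodies
  pos_genes <- truth$genes[truth$genes$clip_rate_npc > 0, ]$id
  assigned <- out$peaks$gene_id[!is.na(out$peaks$gene_id)]
  expect_gt(mean(assigned %in% pos_genes), 0.8)
})
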