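test_that("sim_config validates its parameters", {
  expect_s3_class(sim_config(), "SimConfig")
  expect_error(sim_config(mutant_multiplier = 0), "mutant_multiplier")
  expect_error(sim_config(decay_exponent = 0), "decay_exponent")
  expect_error(sim_config(tad_strength = 0.5), "must be >= 1")
  expect_error(sim_config(chromosomes = c(10)), "names")
})

test_that("planted loop and gene tables are validated", {
  g <- binned_genome("chrT", 5e6, 5000)
  base <- mid_loops()
  bad <- data.table::copy(base); bad$bin_i[1] <- bad$bin_j[1]
  expect_error(loopscape:::validate_planted_loops(bad, g), "bin_i < bin_j")
  bad <- data.table::copy(base); bad$strength[1] <- 0.5
  expect_error(loopscape:::validate_planted_loops(bad, g), "strength")
  bad <- data.table::copy(base); bad$cell_specific[1] <- "HELA"
  expect_error(loopscape:::validate_planted_loops(bad, g), "cell_specific")
  bad <- rbind(base, base[1])
  expect_error(loopscape:::validate_planted_loops(bad, g), "overlapping")
  genes <- data.table::data.table(id = "g1", chrom = "chrT", strand = "+",
                                  tss = 2000L, tes = 1000L, base_mean = 10,
                                  dispersion = 0.1)
  expect_error(loopscape:::validate_planted_genes(genes, g), "orientation")
})

test_that("parse_condition accepts exactly the four study conditions", {
  expect_equal(loopscape:::parse_condition("NPC-mut"),
               list(cell = "NPC", genotype = "mut"))
  expect_error(loopscape:::parse_condition("K562-WT"), "condition")
  expect_error(loopscape:::parse_condition("ESC"), "condition")
})

test_that("realize_truth is deterministic and seed-sensitive", {
  t1 <- realize_truth(mid_cfg())
  t2 <- realize_truth(mid_cfg())
  expect_identical(t1$compartments, t2$compartments)
  expect_identical(t1$tads, t2$tads)
  expect_identical(t1$genes, t2$genes)
  cfg2 <- sim_config(seed = 12L, chromosomes = c(chrT = 5e6),
                     bin_size = 5000, depth = 2e6, compartment_block = 60,
                     tad_size_range = c(20L, 40L), loops = mid_loops())
  t3 <- realize_truth(cfg2)
  expect_false(identical(t1$tads$tad, t3$tads$tad))
})

test_that("compartment labels are TAD-aligned alternating blocks", {
  truth <- mid_truth()
  comp <- truth$compartments
  expect_true(all(comp$label %in% c(-1L, 1L)))
  merged <- merge(comp, truth$tads, by = c("chrom", "bin"))
  per_tad <- merged[, .(n_lab = data.table::uniqueN(label)),
                    by = .(chrom, tad)]
  expect_true(all(per_tad$n_lab == 1L))
  # label runs span at least compartment_block bins (last run may be short)
  r <- rle(comp$label)
  expect_true(all(head(r$lengths, -1) >= mid_cfg()$compartment_block))
  # compartment switches coincide with TAD boundaries
  switch_bins <- comp$bin[which(diff(comp$label) != 0) + 1L]
  expect_true(all(switch_bins %in% truth$tad_boundaries$bin))
})

test_that("simulated contact maps are seeded and loop-enriched", {
  cfg <- mid_cfg()
  truth <- mid_truth()
  a <- simulate_contacts(cfg, "ESC-WT", seed = 5L, truth = truth)$map
  b <- simulate_contacts(cfg, "ESC-WT", seed = 5L, truth = truth)$map
  expect_identical(a$triplets, b$triplets)
  c2 <- simulate_contacts(cfg, "ESC-WT", seed = 6L, truth = truth)$map
  expect_false(identical(a$triplets, c2$triplets))
  # planted ESC-active loop pixels carry their expected intensities
  act <- truth$loops[truth$loops$cell_specific %in% c("ESC", "common"), ]
  px <- data.table::data.table(chrom = act$chrom, bin_i = act$bin_i,
                               bin_j = act$bin_j)
  lam <- loopscape:::expected_lambda(truth, "ESC-WT", px)
  obs <- a$triplets[px, on = c("chrom", "bin_i", "bin_j")]$count
  obs[is.na(obs)] <- 0
  expect_gt(sum(obs), 0.5 * sum(lam))
  expect_lt(sum(obs), 2 * sum(lam))
})

test_that("the mutant attenuates only ZF1-dependent loop pixels", {
  truth <- mid_truth()
  lp <- truth$loops
  px <- data.table::data.table(chrom = lp$chrom, bin_i = lp$bin_i,
                               bin_j = lp$bin_j)
  wt <- loopscape:::expected_lambda(truth, "NPC-WT", px)
  mut <- loopscape:::expected_lambda(truth, "NPC-mut", px)
  dep <- lp$zf1_dependent & lp$cell_specific %in% c("NPC", "common")
  indep <- !lp$zf1_dependent & lp$cell_specific %in% c("NPC", "common")
  # dependent pixels collapse; independent pixels only feel the global
  # depth renormalization (well under 1%)
  expect_true(all(mut[dep] < 0.5 * wt[dep]))
  expect_equal(mut[indep] / wt[indep], rep(1, sum(indep)), tolerance = 0.01)
  # cell-specific loops are inactive in the other cell type
  esc_only <- lp$cell_specific == "ESC"
  in_npc <- loopscape:::expected_lambda(truth, "NPC-WT", px[esc_only])
  in_esc <- loopscape:::expected_lambda(truth, "ESC-WT", px[esc_only])
  expect_true(all(in_npc < in_esc))
})

test_that("expression counts carry the planted condition effects", {
  cfg <- mid_cfg()
  truth <- mid_truth()
  ex <- simulate_expression(cfg, seed = 9L, truth = truth)
  expect_equal(dim(ex$counts),
               c(nrow(truth$genes), 4L * cfg$replicates$expression))
  ex2 <- simulate_expression(cfg, seed = 9L, truth = truth)
  expect_identical(ex$counts, ex2$counts)
  up <- truth$genes$lfc_cell >= 1
  npc <- grepl("^NPC", ex$samples$condition)
  ratio <- rowMeans(ex$counts[, npc]) / pmax(1, rowMeans(ex$counts[, !npc]))
  expect_gt(median(ratio[up]), 2)
  expect_lt(median(ratio[!up & truth$genes$lfc_cell == 0]), 1.5)
})

test_that("ChIP peak simulation places anchor peaks and applies log2fc", {
  cfg <- mid_cfg()
  truth <- mid_truth()
  pk <- simulate_peaks(cfg, cell = "ESC", seed = 3L, truth = truth)
  anchors <- unique(rbind(truth$loops[, c("chrom", "bin_i")],
                          truth$loops[, c("chrom", "bin_j")],
                          use.names = FALSE))
  expect_equal(sum(pk$peaks$type == "anchor"), nrow(anchors))
  expect_equal(ncol(pk$counts), 2L * cfg$replicates$chip)
  # with peak_log2fc = -2 on every peak, mutant counts drop ~4x
  cfg2 <- sim_config(seed = 11L, chromosomes = c(chrT = 5e6),
                     bin_size = 5000, depth = 2e6, compartment_block = 60,
                     tad_size_range = c(20L, 40L), loops = mid_loops(),
                     peak_log2fc = -2)
  pk2 <- simulate_peaks(cfg2, cell = "ESC", seed = 3L)
  wt_cols <- grep("WT", colnames(pk2$counts))
  mut_cols <- grep("mut", colnames(pk2$counts))
  expect_equal(mean(pk2$counts[, mut_cols]) / mean(pk2$counts[, wt_cols]),
               0.25, tolerance = 0.1)
})

test_that("CLIP simulation yields replicate tracks and a clean control", {
  cfg <- mid_cfg()
  truth <- mid_truth()
  sim <- simulate_clip(cfg, cell = "NPC", seed = 8L, truth = truth)
  expect_length(sim$replicates, cfg$replicates$clip)
  expect_true(attr(sim$control, "is_control"))
  # gene-body signal dominates the replicates but not the control
  rep_total <- sum(data.table::as.data.table(sim$replicates[[1]])$count)
  ctl_total <- sum(data.table::as.data.table(sim$control)$count)
  expect_gt(rep_total, 5 * ctl_total)
})

test_that("write_truth emits a readable ground-truth manifest", {
  truth <- mid_truth()
  dir <- tempfile()
  write_truth(truth, dir)
  expect_true(all(file.exists(file.path(
    dir, c("planted_loops.bedpe", "compartments.tsv", "tad_boundaries.tsv",
           "genes.tsv")))))
  lp <- data.table::fread(file.path(dir, "planted_loops.bedpe"))
  expect_equal(nrow(lp), nrow(truth$loops))
  expect_equal(lp$start1 %/% truth$genome$bin_size, truth$loops$bin_i)
})
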