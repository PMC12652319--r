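pipeline_config_schema <- list(
  seed = NULL,
  genome = c("chromosomes", "bin_size"),
  simulate = c("depth", "decay_exponent", "decay_offset", "compartment_block",
               "compartment_strength", "tad_size_range", "tad_strength",
               "mutant_multiplier", "n_background_peaks", "clip_background",
               "contact_replicates", "expression_replicates", "chip_replicates",
               "clip_replicates"),
  loops = c("fdr", "min_sep", "max_sep"),
  diff = c("fdr", "lfc", "pseudocount"),
  scores = c("apa_w", "apa_corner", "insulation_window",
             "boundary_prominence", "scc_h", "scc_max_dist"),
  clip = c("bg_window", "alpha", "gap", "width", "percentile",
           "min_required", "control_overlap"),
  de = c("rna_lfc", "chip_lfc", "clip_lfc", "alpha"),
  enrich = c("n_random", "promoter_window", "upstream"),
  output = c("write_maps"))

check_config_keys <- function(cfg) {
  bad <- setdiff(names(cfg), names(pipeline_config_schema))
  if (length(bad)) stop("unknown config key: ", bad[1])
  for (sec in names(cfg)) {
    allowed <- pipeline_config_schema[[sec]]
    if (is.null(allowed)) next
    extra <- setdiff(names(cfg[[sec]]), allowed)
    if (length(extra)) stop("unknown config key: ", sec, ".", extra[1])
  }
}

#' Read and validate a pipeline configuration file
#'
#' YAML with sections `seed`, `genome`, `simulate`, `loops`, `diff`,
#' `scores`, `clip`, `de`, `enrich`, `output`; every threshold defaults to
#' the package default when omitted.  Unknown keys raise an error naming
#' the offending key.
#'
#' @param path YAML file path.
#' @return list with `sim` (a [sim_config()]) and `params` (the resolved
#'   per-stage parameter list).
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  check_config_keys(cfg)
  gv <- function(sec, key, default) {
    v <- cfg[[sec]][[key]]
    if (is.null(v)) default else v
  }
  chroms <- cfg$genome$chromosomes
  if (is.null(chroms)) chroms <- list(chrSim1 = 2e7, chrSim2 = 2e7)
  chroms <- unlist(chroms)
  chroms <- stats::setNames(as.numeric(chroms), names(chroms))  # YAML "2.0e7" arrives as character
  sim <- sim_config(
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed),
    chromosomes = chroms,
    bin_size = as.numeric(gv("genome", "bin_size", 5000)),
    depth = as.numeric(gv("simulate", "depth", 2e7)),
    decay_exponent = gv("simulate", "decay_exponent", 1),
    decay_offset = gv("simulate", "decay_offset", 5),
    compartment_block = gv("simulate", "compartment_block", 100),
    compartment_strength = gv("simulate", "compartment_strength", 1.4),
    tad_size_range = unlist(gv("simulate", "tad_size_range", c(40L, 80L))),
    tad_strength = gv("simulate", "tad_strength", 1.6),
    mutant_multiplier = gv("simulate", "mutant_multiplier", 0.15),
    n_background_peaks = gv("simulate", "n_background_peaks", 300L),
    clip = list(background = gv("simulate", "clip_background", 5e-5),
                control_rate = gv("simulate", "clip_background", 5e-5)),
    replicates = list(
      contacts = gv("simulate", "contact_replicates", 2L),
      expression = gv("simulate", "expression_replicates", 3L),
      chip = gv("simulate", "chip_replicates", 3L),
      clip = gv("simulate", "clip_replicates", 4L)))
  params <- list(
    loops = list(fdr = gv("loops", "fdr", 0.01),
                 min_sep = gv("loops", "min_sep", 2L),
                 max_sep = gv("loops", "max_sep", 400L)),
    diff = list(fdr = gv("diff", "fdr", 0.01), lfc = gv("diff", "lfc", 1),
                pc = gv("diff", "pseudocount", 1)),
    scores = list(apa_w = gv("scores", "apa_w", 10L),
                  apa_corner = gv("scores", "apa_corner", 6L),
                  insulation_window = gv("scores", "insulation_window", 10L),
                  boundary_prominence = gv("scores", "boundary_prominence", 0.1),
                  scc_h = gv("scores", "scc_h", 1L),
                  scc_max_dist = gv("scores", "scc_max_dist", 400L)),
    clip = list(bg_window = gv("clip", "bg_window", 20001L),
                alpha = gv("clip", "alpha", 0.01),
                gap = gv("clip", "gap", 15L),
                width = gv("clip", "width", 300L),
                percentile = gv("clip", "percentile", 10),
                min_required = gv("clip", "min_required", 3L),
                control_overlap = gv("clip", "control_overlap", 0.20)),
    de = list(rna_lfc = gv("de", "rna_lfc", 0.5),
              chip_lfc = gv("de", "chip_lfc", 1),
              clip_lfc = gv("de", "clip_lfc", 1),
              alpha = gv("de", "alpha", 0.05)),
    enrich = list(n_random = gv("enrich", "n_random", 2L),
                  promoter_window = gv("enrich", "promoter_window", 1000),
                  upstream = gv("enrich", "upstream", 1000)),
    write_maps = isTRUE(gv("output", "write_maps", FALSE)))
  list(sim = sim, params = params)
}

#' Write the default pipeline configuration
#'
#' Emits a YAML config with every stage parameter at its package default,
#' as a template for [run_pipeline()].
#'
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_default_config <- function(path) {
  cfg <- list(
    seed = 1L,
    genome = list(chromosomes = list(chrSim1 = 2e7, chrSim2 = 2e7),
                  bin_size = 5000L),
    simulate = list(depth = 2e7, decay_exponent = 1, decay_offset = 5,
                    compartment_block = 100L, compartment_strength = 1.4,
                    tad_size_range = c(40L, 80L), tad_strength = 1.6,
                    mutant_multiplier = 0.15, n_background_peaks = 300L,
                    clip_background = 5e-5, contact_replicates = 2L,
                    expression_replicates = 3L, chip_replicates = 3L,
                    clip_replicates = 4L),
    loops = list(fdr = 0.01, min_sep = 2L, max_sep = 400L),
    diff = list(fdr = 0.01, lfc = 1, pseudocount = 1),
    scores = list(apa_w = 10L, apa_corner = 6L, insulation_window = 10L,
                  boundary_prominence = 0.1, scc_h = 1L, scc_max_dist = 400L),
    clip = list(bg_window = 20001L, alpha = 0.01, gap = 15L, width = 300L,
                percentile = 10, min_required = 3L, control_overlap = 0.20),
    de = list(rna_lfc = 0.5, chip_lfc = 1, clip_lfc = 1, alpha = 0.05),
    enrich = list(n_random = 2L, promoter_window = 1000, upstream = 1000),
    output = list(write_maps = FALSE))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full synthetic WT-vs-mutant, ESC-vs-NPC workflow
#'
#' Executes all stages in dependency order: ground-truth realization,
#' contact simulation for the four conditions, depth matching
#' (downsampling), ICE balancing, loop calling, WT-vs-mutant and
#' ESC-vs-NPC differential classification, architecture scores (APA,
#' insulation, SCC between two wild-type replicates, compartments), ChIP
#' peak and expression differential tests, the CLIP peak pipeline and
#' differential CLIP genes, enrichment statistics, and the three-way
#' candidate-RNA intersection.  Every output file is recorded in the
#' manifest with an MD5 checksum; the run is fully determined by the
#' config (including its seed).
#'
#' @param config_path YAML config path (see [write_default_config()]).
#' @param outdir output directory (created).
#' @param quiet suppress per-stage progress messages.
#' @return An object of class `RunManifest` (also written to
#'   `manifest.json` in `outdir`): list with `config_hash`, `seed`,
#'   `stages` (per-stage parameters, outputs with checksums, record
#'   counts, wall times) and `summary` (headline numbers).
#' @export
run_pipeline <- function(config_path, outdir, quiet = FALSE) {
  conf <- read_pipeline_config(config_path)
  sim <- conf$sim; pp <- conf$params
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("loopscape")),
    config_hash = unname(tools::md5sum(config_path)),
    seed = sim$seed, stages = list(), summary = list())
  say <- function(...) if (!quiet) message(sprintf(...))
  t_all <- Sys.time()
  add_stage <- function(name, params, outputs, n_records, t0) {
    manifest$stages[[name]] <<- list(
      params = params,
      outputs = lapply(outputs, function(p)
        list(path = sub("^/+", "", substring(p, nchar(outdir) + 1L)),
             md5 = unname(tools::md5sum(p)))),
      n_records = n_records,
      wall_seconds = round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 2))
    say("[%s] done in %.1fs", name,
        manifest$stages[[name]]$wall_seconds)
  }
  finish <- function(ok) {
    manifest$completed <<- ok
    manifest$total_seconds <<-
      round(as.numeric(difftime(Sys.time(), t_all, units = "secs")), 2)
    path <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    path
  }
  tryCatch({
    ## ground truth ----------------------------------------------------
    t0 <- Sys.time()
    truth <- realize_truth(sim)
    tdir <- file.path(outdir, "truth")
    write_truth(truth, tdir)
    add_stage("truth", list(seed = sim$seed),
              file.path(tdir, c("planted_loops.bedpe", "compartments.tsv",
                                "tad_boundaries.tsv", "genes.tsv")),
              nrow(truth$loops), t0)

    ## contact maps ----------------------------------------------------
    t0 <- Sys.time()
    conds <- sim_conditions()
    maps <- list()
    for (k in seq_along(conds))
      maps[[conds[k]]] <- simulate_contacts(sim, conds[k],
                                            seed = sim$seed + 10L + k,
                                            truth = truth)$map
    rep2 <- simulate_contacts(sim, "ESC-WT", seed = sim$seed + 20L,
                              truth = truth)$map
    map_files <- character(0)
    if (pp$write_maps) {
      for (cn in conds) {
        f <- file.path(outdir, paste0("contacts_", cn, ".tsv"))
        write_contacts(maps[[cn]], f)
        map_files <- c(map_files, f)
      }
    }
    add_stage("simulate_contacts",
              list(conditions = conds, depth = sim$depth),
              map_files, sum(vapply(maps, function(m) nrow(m$triplets),
                                    numeric(1))), t0)

    ## depth matching + balancing --------------------------------------
    t0 <- Sys.time()
    # thin in place (one transient copy at a time) to keep the peak
    # footprint at ~one extra map instead of two full lists
    target <- min(vapply(maps, function(m) m$total_valid_pairs, numeric(1)))
    set.seed(as.integer(sim$seed + 30L))
    for (cn in conds) maps[[cn]] <- downsample_one(maps[[cn]], target)
    weights <- lapply(maps, ice_balance)
    add_stage("normalize", list(target = maps[[1]]$total_valid_pairs),
              character(0), length(maps), t0)

    ## loop calling ----------------------------------------------------
    t0 <- Sys.time()
    calls <- list(); loop_files <- character(0)
    for (cn in conds) {
      prof <- expected_by_distance(maps[[cn]])
      calls[[cn]] <- call_loops(maps[[cn]], prof, fdr = pp$loops$fdr,
                                min_sep = pp$loops$min_sep,
                                max_sep = pp$loops$max_sep, condition = cn)
      f <- file.path(outdir, paste0("loops_", cn, ".bedpe"))
      write_bedpe(calls[[cn]], f)
      loop_files <- c(loop_files, f)
    }
    add_stage("call_loops", pp$loops, loop_files,
              sum(vapply(calls, function(x) nrow(x$loops), numeric(1))), t0)

    ## differential loops ----------------------------------------------
    t0 <- Sys.time()
    diffs <- list(
      ESC = classify_differential(calls[["ESC-WT"]], calls[["ESC-mut"]],
                                  fdr = pp$diff$fdr, lfc = pp$diff$lfc,
                                  pc = pp$diff$pc),
      NPC = classify_differential(calls[["NPC-WT"]], calls[["NPC-mut"]],
                                  fdr = pp$diff$fdr, lfc = pp$diff$lfc,
                                  pc = pp$diff$pc),
      cell = classify_differential(calls[["ESC-WT"]], calls[["NPC-WT"]],
                                   fdr = pp$diff$fdr, lfc = pp$diff$lfc,
                                   pc = pp$diff$pc))
    diff_files <- character(0)
    for (nm in names(diffs)) {
      f <- file.path(outdir, paste0("diff_loops_", nm, ".bedpe"))
      write_bedpe(data.table::as.data.table(diffs[[nm]]), f,
                  genome = truth$genome)
      diff_files <- c(diff_files, f)
    }
    add_stage("diff_loops", pp$diff, diff_files,
              sum(vapply(diffs, nrow, numeric(1))), t0)
    # everything downstream only needs the ESC-WT map/weights/calls
    loop_counts <- lapply(calls, function(x) nrow(x$loops))
    maps <- maps["ESC-WT"]
    weights <- weights["ESC-WT"]
    calls <- calls["ESC-WT"]
    invisible(gc(FALSE))

    ## ChIP peaks ------------------------------------------------------
    t0 <- Sys.time()
    chip <- simulate_peaks(sim, cell = "ESC", seed = sim$seed + 31L,
                           truth = truth)
    peak_file <- file.path(outdir, "ctcf_peaks.bed")
    write_bed(chip$peaks[, .(chrom, start, end, name)], peak_file)
    chip_de <- nb_test(chip$counts,
                       rep(c("WT", "mut"), each = sim$replicates$chip),
                       lfc_threshold = pp$de$chip_lfc, alpha = pp$de$alpha)
    chip_de_file <- file.path(outdir, "chip_differential.tsv")
    write_differential(chip_de, chip_de_file)
    add_stage("chip", list(lfc = pp$de$chip_lfc, alpha = pp$de$alpha),
              c(peak_file, chip_de_file), nrow(chip$peaks), t0)

    ## scores ----------------------------------------------------------
    t0 <- Sys.time()
    wt <- maps[["ESC-WT"]]
    wt_w <- weights[["ESC-WT"]]
    wt_prof_bal <- expected_by_distance(wt, wt_w)
    apa_res <- apa(wt, wt_w, wt_prof_bal, calls[["ESC-WT"]],
                   w = pp$scores$apa_w, corner = pp$scores$apa_corner)
    ins <- insulation(wt, wt_w, window = pp$scores$insulation_window,
                      min_prominence = pp$scores$boundary_prominence)
    ins_file <- file.path(outdir, "insulation_ESC-WT.tsv")
    data.table::fwrite(data.table::as.data.table(ins), ins_file, sep = "\t")
    scc_res <- scc(maps[["ESC-WT"]], rep2, h = pp$scores$scc_h,
                   max_dist_bins = pp$scores$scc_max_dist)
    comp <- compartment_eigenvector(
      wt, wt_w, wt_prof_bal,
      truth$compartments[, .(chrom, bin, value = label)])
    comp_file <- file.path(outdir, "compartments_ESC-WT.tsv")
    data.table::fwrite(data.table::as.data.table(comp), comp_file, sep = "\t")
    score_file <- file.path(outdir, "scores.tsv")
    data.table::fwrite(data.table::data.table(
      metric = c("apa_score", paste0("scc_", names(scc_res$scc))),
      value = c(apa_res$score, unname(scc_res$scc))), score_file, sep = "\t")
    add_stage("scores", pp$scores, c(ins_file, comp_file, score_file),
              nrow(ins), t0)
    rm(wt, wt_w, wt_prof_bal, comp, rep2)
    maps <- NULL; weights <- NULL; calls <- NULL
    invisible(gc(FALSE))

    ## expression ------------------------------------------------------
    t0 <- Sys.time()
    expr <- simulate_expression(sim, seed = sim$seed + 41L, truth = truth)
    pick <- function(cond) expr$samples$condition == cond
    rna_cell <- nb_test(expr$counts[, pick("ESC-WT") | pick("NPC-WT")],
                        expr$samples$condition[pick("ESC-WT") | pick("NPC-WT")],
                        lfc_threshold = pp$de$rna_lfc, alpha = pp$de$alpha)
    rna_mut <- nb_test(expr$counts[, pick("NPC-WT") | pick("NPC-mut")],
                       expr$samples$condition[pick("NPC-WT") | pick("NPC-mut")],
                       lfc_threshold = pp$de$rna_lfc, alpha = pp$de$alpha)
    rna_files <- file.path(outdir, c("rna_cell_differential.tsv",
                                     "rna_mut_differential.tsv"))
    write_differential(rna_cell, rna_files[1])
    write_differential(rna_mut, rna_files[2])
    add_stage("expression", list(lfc = pp$de$rna_lfc, alpha = pp$de$alpha),
              rna_files, nrow(rna_cell), t0)

    ## CLIP ------------------------------------------------------------
    t0 <- Sys.time()
    clip_npc <- simulate_clip(sim, cell = "NPC", seed = sim$seed + 51L,
                              truth = truth)
    clip_esc <- simulate_clip(sim, cell = "ESC", seed = sim$seed + 52L,
                              truth = truth)
    cp <- clip_peaks(clip_npc$replicates, clip_npc$control,
                     genes = truth$genes, bg_window = pp$clip$bg_window,
                     alpha = pp$clip$alpha, gap = pp$clip$gap,
                     width = pp$clip$width, percentile = pp$clip$percentile,
                     min_required = pp$clip$min_required,
                     max_overlap_fraction = pp$clip$control_overlap)
    clip_file <- file.path(outdir, "clip_peaks_NPC.bed")
    write_bed(cp$peaks[, .(chrom, start, end, name, score = summit_count,
                           strand)], clip_file)
    tracks <- c(stats::setNames(clip_esc$replicates,
                                sprintf("ESC_r%d", seq_along(clip_esc$replicates))),
                stats::setNames(clip_npc$replicates,
                                sprintf("NPC_r%d", seq_along(clip_npc$replicates))))
    gc_counts <- clip_gene_counts(truth$genes, tracks)
    clip_de <- differential_clip_genes(
      gc_counts, rep(c("ESC", "NPC"), times = c(length(clip_esc$replicates),
                                                length(clip_npc$replicates))),
      lfc_threshold = pp$de$clip_lfc, alpha = pp$de$alpha)
    clip_de_file <- file.path(outdir, "clip_differential.tsv")
    write_differential(clip_de, clip_de_file)
    add_stage("clip", pp$clip, c(clip_file, clip_de_file), nrow(cp$peaks), t0)

    ## enrichment + candidates -----------------------------------------
    t0 <- Sys.time()
    npc <- diffs$NPC
    cellc <- diffs$cell
    lab <- cellc[npc, on = c("chrom", "bin_i", "bin_j")]$class
    spec <- data.table::fifelse(is.na(lab), "common",
              data.table::fifelse(lab == "B_specific", "cell_specific", "common"))
    enr <- tryCatch(cell_specific_loss_enrichment(npc, spec),
                    error = function(e) NULL)
    lost <- npc[class == "A_specific"]
    dys <- rna_mut$feature[rna_mut$significant]
    coloc <- if (nrow(lost) && length(dys))
      gene_loop_colocalization(dys, truth$genes, lost, truth$genome,
                               mode = "anchor", n_random = pp$enrich$n_random,
                               seed = sim$seed) else NULL
    up_npc <- rna_cell$feature[rna_cell$significant & rna_cell$log2FC > 0]
    clip_npc_genes <- clip_de$feature[clip_de$significant & clip_de$log2FC > 0]
    npc_spec_loops <- cellc[class == "B_specific"]
    coloc_all <- if (nrow(npc_spec_loops))
      gene_loop_colocalization(truth$genes$id, truth$genes, npc_spec_loops,
                               truth$genome, mode = "anchor",
                               n_random = pp$enrich$n_random,
                               seed = sim$seed) else NULL
    coloc_genes <- if (is.null(coloc_all)) character(0) else
      names(coloc_all$flags)[coloc_all$flags]
    cand <- candidate_rnas(up_npc, coloc_genes, clip_npc_genes,
                           genes = truth$genes, loops = npc_spec_loops,
                           genome = truth$genome)
    cand_file <- file.path(outdir, "candidates.tsv")
    data.table::fwrite(data.table::data.table(gene = cand$candidates),
                       cand_file, sep = "\t")
    enrich_file <- file.path(outdir, "enrichment.json")
    jsonlite::write_json(list(
      cell_specific_loss = if (is.null(enr)) NULL else
        list(table = enr$table, odds_ratio = enr$odds_ratio,
             p_value = enr$p_value),
      dysregulated_colocalization = if (is.null(coloc)) NULL else
        list(fraction = coloc$fraction,
             random_fractions = coloc$random_fractions,
             odds_ratio = coloc$test$odds_ratio,
             p_value = coloc$test$p_value),
      promoter_window = pp$enrich$promoter_window),
      enrich_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    add_stage("enrichment", pp$enrich, c(cand_file, enrich_file),
              cand$n_candidates, t0)

    ## summary ---------------------------------------------------------
    manifest$summary <- list(
      loop_counts = loop_counts,
      lost_fraction_ESC = if (nrow(diffs$ESC))
        mean(diffs$ESC$class == "A_specific") else NA,
      lost_fraction_NPC = if (nrow(diffs$NPC))
        mean(diffs$NPC$class == "A_specific") else NA,
      apa_score = apa_res$score,
      scc = as.list(scc_res$scc),
      boundary_count = nrow(boundaries(ins)),
      clip_reproducible_peaks = nrow(cp$peaks),
      n_candidates = cand$n_candidates)
    path <- finish(TRUE)
    say("pipeline complete: %s", path)
    invisible(structure(manifest, class = "RunManifest"))
  }, error = function(e) {
    finish(FALSE)
    stop(e)
  })
}
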