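#' Simulation configuration for the synthetic 3D-genome generator
#'
#' Describes a desk-scale two-condition study: a distance-decaying contact
#' map with planted A/B compartments, TADs and loops (a subset of which
#' weakens in the "mutant" genotype), condition-invariant CTCF/cohesin
#' peaks, negative-binomial expression counts with condition effects, and
#' replicated strand-specific crosslink tracks with a non-crosslinked
#' control.  Two cell states (`ESC`, `NPC`) times two genotypes (`WT`,
#' `mut`) are modelled; planted loops carry a `cell_specific` label and a
#' `zf1_dependent` flag whose strength is attenuated by
#' `mutant_multiplier` in the mutant genotype.
#'
#' The expected intensity of bin pair `(a, b)` at distance `d = |a - b|` is
#' `lambda = depth * Z^-1 * (d0 + d)^-alpha * C(a,b) * T(a,b) * L(a,b)`
#' with `C` the compartment plaid factor (`compartment_strength` if the two
#' bins share an A/B label, its reciprocal otherwise), `T` the TAD factor
#' (`tad_strength` within a TAD), `L` the loop factor (a 3x3
#' Gaussian-tapered peak: exponent 1 at the centre pixel, 0.5 at the eight
#' neighbours), and `Z` normalising the per-chromosome total to `depth`.
#' Observed counts are independent Poisson draws.
#'
#' Defaults describe the package's reference study: 2 chromosomes x 20 Mb
#' at 5-kb bins, depth 2e7 contacts per chromosome, 500-kb compartment
#' blocks at strength 1.4, 200-400-kb TADs at strength 1.6, and 24 planted
#' loops per chromosome (10 ZF1-dependent at 0.7-1.05 Mb span, 14
#' independent at 0.15-0.55 Mb).
#'
#' @param seed integer; seeds the deterministic realization of planted
#'   features (loops, genes, TAD boundaries).
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param bin_size bin width in bp.
#' @param decay_exponent alpha > 0 of the power-law distance decay.
#' @param decay_offset d0 (bins) of the decay `(d0 + d)^-alpha`.
#' @param depth expected total contacts per chromosome.
#' @param compartment_block bins per alternating A/B block.
#' @param compartment_strength multiplicative plaid factor (>= 1).
#' @param tad_size_range integer range of TAD sizes in bins.
#' @param tad_strength multiplicative within-TAD factor (>= 1).
#' @param mutant_multiplier factor applied to `strength` of ZF1-dependent
#'   loops in the mutant genotype (floored so strength never drops below 1).
#' @param loops optional data.frame of planted loops (`chrom`, `bin_i`,
#'   `bin_j`, `strength`, `zf1_dependent`, `cell_specific`); `NULL` plants
#'   the default set.
#' @param genes optional data.frame of planted genes (`id`, `chrom`,
#'   `strand`, `tss`, `tes`, `base_mean`, `dispersion`, `lfc_cell`,
#'   `lfc_mut_esc`, `lfc_mut_npc`, `clip_rate_esc`, `clip_rate_npc`);
#'   `NULL` plants the default set.
#' @param clip list: `background` (events per nt per replicate genome-wide,
#'   both strands) and `control_rate` for the non-crosslinked control.
#' @param replicates list of replicate counts per assay:
#'   `contacts`, `expression`, `chip`, `clip`.
#' @param n_background_peaks background CTCF peak sites per chromosome.
#' @param peak_base_mean,peak_dispersion NB parameters for ChIP peak counts.
#' @param peak_log2fc optional per-peak log2 fold change (mutant vs WT),
#'   length 1 or number of peaks; default no differential peaks.
#' @param size_factor_range range of per-sample expression size factors
#'   (drawn log-uniform).
#' @return an object of class `SimConfig`.
#' @export
sim_config <- function(seed = 1L,
                       chromosomes = c(chrSim1 = 2e7, chrSim2 = 2e7),
                       bin_size = 5000,
                       decay_exponent = 1,
                       decay_offset = 5,
                       depth = 2e7,
                       compartment_block = 100,
                       compartment_strength = 1.4,
                       tad_size_range = c(40L, 80L),
                       tad_strength = 1.6,
                       mutant_multiplier = 0.15,
                       loops = NULL,
                       genes = NULL,
                       clip = list(background = 5e-5, control_rate = 5e-5),
                       replicates = list(contacts = 2L, expression = 3L,
                                         chip = 3L, clip = 4L),
                       n_background_peaks = 300L,
                       peak_base_mean = 100,
                       peak_dispersion = 0.05,
                       peak_log2fc = NULL,
                       size_factor_range = c(0.7, 1.4)) {
  cfg <- structure(as.list(environment()), class = "SimConfig")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(length(cfg$chromosomes) >= 1, !is.null(names(cfg$chromosomes)),
            all(cfg$chromosomes > 0))
  if (cfg$decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (cfg$depth <= 0) stop("depth must be > 0")
  if (cfg$compartment_strength < 1 || cfg$tad_strength < 1)
    stop("compartment_strength and tad_strength must be >= 1")
  if (cfg$mutant_multiplier <= 0) stop("mutant_multiplier must be > 0")
  genome <- sim_genome(cfg)
  if (!is.null(cfg$loops)) validate_planted_loops(cfg$loops, genome)
  if (!is.null(cfg$genes)) validate_planted_genes(cfg$genes, genome)
  invisible(cfg)
}

validate_planted_loops <- function(loops, genome) {
  loops <- data.table::as.data.table(loops)
  need <- c("chrom", "bin_i", "bin_j", "strength", "zf1_dependent", "cell_specific")
  if (!all(need %in% names(loops)))
    stop("planted loops need columns: ", paste(need, collapse = ", "))
  check_chrom(genome, loops$chrom)
  if (any(loops$strength < 1)) stop("planted loop strength must be >= 1")
  if (any(loops$bin_i >= loops$bin_j)) stop("planted loops require bin_i < bin_j")
  if (any(loops$bin_j - loops$bin_i < 2))
    stop("planted loop anchors must be separated by >= 2 bins")
  nb <- genome$n_bins[loops$chrom]
  if (any(loops$bin_i < 0) || any(loops$bin_j >= nb))
    stop("planted loop outside chromosome bounds")
  if (anyDuplicated(loops[, c("chrom", "bin_i", "bin_j")]))
    stop("overlapping planted loops at identical bin pairs")
  if (!all(loops$cell_specific %in% c("ESC", "NPC", "common")))
    stop("cell_specific must be ESC, NPC or common")
  invisible(loops)
}

validate_planted_genes <- function(genes, genome) {
  genes <- data.table::as.data.table(genes)
  need <- c("id", "chrom", "strand", "tss", "tes", "base_mean", "dispersion")
  if (!all(need %in% names(genes)))
    stop("planted genes need columns: ", paste(need, collapse = ", "))
  check_chrom(genome, genes$chrom)
  if (any(genes$tss == genes$tes)) stop("gene TSS must differ from TES")
  if (any(genes$base_mean <= 0)) stop("base_mean must be > 0")
  if (any(genes$dispersion < 0)) stop("dispersion must be >= 0")
  if (any(genes$strand == "+" & genes$tss >= genes$tes) ||
      any(genes$strand == "-" & genes$tss <= genes$tes))
    stop("TSS/TES orientation inconsistent with strand")
  invisible(genes)
}

sim_genome <- function(cfg) {
  binned_genome(names(cfg$chromosomes), unname(cfg$chromosomes), cfg$bin_size)
}

sim_conditions <- function() {
  c("ESC-WT", "ESC-mut", "NPC-WT", "NPC-mut")
}

parse_condition <- function(condition) {
  parts <- strsplit(condition, "-", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% c("ESC", "NPC") ||
      !parts[2] %in% c("WT", "mut"))
    stop("condition must be one of ", paste(sim_conditions(), collapse = ", "))
  list(cell = parts[1], genotype = parts[2])
}

# run expr with an isolated, seeded RNG stream; restores the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(as.integer(seed))
  expr
}

#' Realize the planted ground truth of a simulation config
#'
#' Deterministically (from `config$seed`) lays out compartment labels, TAD
#' boundaries, planted loops and planted genes.  The result is the oracle
#' against which parameter recovery is scored.
#'
#' @param config a [sim_config()].
#' @return An object of class `GroundTruth`: list with `genome`,
#'   `compartments` (`chrom`, `bin`, `label` in +-1, A = +1),
#'   `tads` (`chrom`, `bin`, `tad`), `tad_boundaries` (`chrom`, `bin`),
#'   `loops`, `genes` and the generating `config`.
#' @export
realize_truth <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  genome <- sim_genome(config)
  with_seed(config$seed, {
    comp <- list(); tads <- list(); bdry <- list()
    for (cn in genome$chrom) {
      n <- genome$n_bins[[cn]]
      sizes <- integer(0)
      while (sum(sizes) < n)
        sizes <- c(sizes, sample(config$tad_size_range[1]:config$tad_size_range[2], 1))
      tid <- rep(seq_along(sizes), sizes)[1:n]
      # compartment blocks are alternating runs of whole TADs of at least
      # compartment_block bins: compartment switches coincide with TAD
      # boundaries, as they do in real genomes
      tad_lab <- integer(length(sizes))
      cur <- 1L; run <- 0L
      for (t in seq_along(sizes)) {
        tad_lab[t] <- cur
        run <- run + sizes[t]
        if (run >= config$compartment_block) { cur <- -cur; run <- 0L }
      }
      lab <- tad_lab[tid]
      comp[[cn]] <- data.table::data.table(chrom = cn, bin = 0:(n - 1L), label = lab)
      tads[[cn]] <- data.table::data.table(chrom = cn, bin = 0:(n - 1L), tad = tid)
      bd <- which(diff(tid) != 0)  # boundary between bin bd-1 and bd (0-based bd)
      bdry[[cn]] <- data.table::data.table(chrom = cn, bin = bd)
    }
    loops <- if (is.null(config$loops)) default_planted_loops(genome) else
      validate_planted_loops(config$loops, genome)
    loops <- data.table::as.data.table(loops)
    loops[, id := sprintf("loop_%03d", seq_len(.N))]
    genes <- if (is.null(config$genes)) default_planted_genes(genome, loops) else
      validate_planted_genes(config$genes, genome)
    genes <- data.table::as.data.table(genes)
    for (col in c("lfc_cell", "lfc_mut_esc", "lfc_mut_npc",
                  "clip_rate_esc", "clip_rate_npc"))
      if (is.null(genes[[col]])) genes[, (col) := 0]
    structure(list(genome = genome,
                   compartments = data.table::rbindlist(comp),
                   tads = data.table::rbindlist(tads),
                   tad_boundaries = data.table::rbindlist(bdry),
                   loops = loops, genes = genes, config = config),
              class = "GroundTruth")
  })
}

# Default planted loop set per chromosome: 10 ZF1-dependent loops at long
# range (140-210 bins) with strengths 8-9, 14 independent loops at short
# range (30-110 bins) with strengths 6-9.  Anchor sites are spaced >= 5
# bins so tapered neighbourhoods never collide.  Dependent loops are
# preferentially cell-specific (NPC-skewed), mirroring the preferential
# loss of cell-specific loops.
default_planted_loops <- function(genome) {
  out <- list()
  for (cn in genome$chrom) {
    n <- genome$n_bins[[cn]]
    lo <- 200L; hi <- n - 300L
    pick_sites <- function(k, existing) {
      sites <- integer(0)
      while (length(sites) < k) {
        cand <- sample(lo:hi, 1)
        if (all(abs(cand - c(sites, existing)) >= 5)) sites <- c(sites, cand)
      }
      sort(sites)
    }
    di <- pick_sites(10, integer(0))
    dd <- sample(140:210, 10, replace = TRUE)
    dep <- data.table::data.table(chrom = cn, bin_i = di, bin_j = di + dd,
                                  strength = sample(8:9, 10, replace = TRUE),
                                  zf1_dependent = TRUE,
                                  cell_specific = sample(c(rep("NPC", 5), rep("ESC", 2),
                                                           rep("common", 3))))
    ii <- pick_sites(14, c(di, di + dd))
    id <- sample(30:110, 14, replace = TRUE)
    ind <- data.table::data.table(chrom = cn, bin_i = ii, bin_j = ii + id,
                                  strength = sample(6:9, 14, replace = TRUE),
                                  zf1_dependent = FALSE,
                                  cell_specific = sample(c(rep("NPC", 3), rep("ESC", 3),
                                                           rep("common", 8))))
    out[[cn]] <- rbind(dep, ind)
  }
  data.table::rbindlist(out)
}

# Default planted gene set: 150 genes per chromosome on a jittered grid,
# 2-4 kb long.  Subsets get planted effects:
#   - "triple" genes sit on NPC-specific loop anchors, are NPC-upregulated
#     (lfc_cell = +2) and NPC-CLIP-positive (0.08 events/nt/replicate);
#   - further genes carry single or double memberships so the three-way
#     intersection is non-trivial;
#   - 50 genes are mutant-dysregulated in NPC, 20 in ESC (|lfc| = 1.5).
default_planted_genes <- function(genome, loops) {
  bs <- genome$bin_size
  gl <- list(); gid <- 0L
  for (cn in genome$chrom) {
    len <- unname(genome$length[[cn]])
    k <- 150L
    anchor0 <- floor(seq(2e5, len - 2e5, length.out = k))
    start <- anchor0 + sample(-5e4:5e4, k, replace = TRUE)
    width <- sample(2000:4000, k, replace = TRUE)
    strand <- sample(c("+", "-"), k, replace = TRUE)
    gl[[cn]] <- data.table::data.table(chrom = cn, start = start,
                                       end = start + width, strand = strand)
  }
  g <- data.table::rbindlist(gl)
  g[, id := sprintf("gene_%04d", seq_len(.N))]
  # membership bookkeeping
  g[, `:=`(lfc_cell = 0, lfc_mut_esc = 0, lfc_mut_npc = 0,
           clip_rate_esc = 0, clip_rate_npc = 0)]
  npc_anchors <- rbind(
    loops[cell_specific == "NPC", .(chrom, bin = bin_i)],
    loops[cell_specific == "NPC", .(chrom, bin = bin_j)])
  npc_anchors <- unique(npc_anchors)
  npc_anchors <- npc_anchors[sample(.N)]
  place_at_anchor <- function(idx, arow) {
    # put the gene body inside the anchor bin
    s <- arow$bin * bs + 500
    w <- g$end[idx] - g$start[idx]
    g[idx, `:=`(chrom = arow$chrom, start = s, end = s + min(w, bs - 1000))]
  }
  all_idx <- sample(nrow(g))
  take <- function(k) {
    if (k == 0L) return(integer(0))   # x[-integer(0)] would drop everything
    out <- all_idx[seq_len(k)]
    all_idx <<- all_idx[-seq_len(k)]
    out
  }
  # anchor-placed sets shrink when a small genome has few NPC-specific anchors
  n_triple <- min(12L, nrow(npc_anchors))
  n_coloc <- min(8L, nrow(npc_anchors) - n_triple)
  triple <- take(n_triple)
  for (t in seq_along(triple)) place_at_anchor(triple[t], npc_anchors[t])
  g[, set := "background"]
  g[triple, `:=`(lfc_cell = 2, clip_rate_npc = 0.08, set = "triple")]
  coloc_up <- take(n_coloc)   # at anchors + upregulated, no CLIP
  for (t in seq_along(coloc_up)) place_at_anchor(coloc_up[t], npc_anchors[n_triple + t])
  g[coloc_up, `:=`(lfc_cell = 2, set = "coloc_up")]
  clip_up <- take(18)   # CLIP + upregulated, away from anchors
  g[clip_up, `:=`(lfc_cell = 2, clip_rate_npc = 0.08, set = "clip_up")]
  clip_only <- take(10)
  g[clip_only, `:=`(clip_rate_npc = 0.08, set = "clip_only")]
  up_only <- take(30)
  g[up_only, `:=`(lfc_cell = 2, set = "up_only")]
  dys_npc <- take(50)
  g[dys_npc, `:=`(lfc_mut_npc = sample(c(-1.5, 1.5), 50, replace = TRUE),
                  set = "dys_npc")]
  dys_esc <- take(20)
  g[dys_esc, `:=`(lfc_mut_esc = sample(c(-1.5, 1.5), 20, replace = TRUE),
                  set = "dys_esc")]
  g[, `:=`(base_mean = exp(stats::rnorm(.N, log(200), 0.5)), dispersion = 0.05)]
  g[, `:=`(tss = ifelse(strand == "+", start, end),
           tes = ifelse(strand == "+", end, start))]
  g[, c("start", "end") := NULL]
  data.table::setcolorder(g, c("id", "chrom", "strand", "tss", "tes",
                               "base_mean", "dispersion"))
  g[]
}

loop_active <- function(loops, cell) {
  loops$cell_specific == "common" | loops$cell_specific == cell
}

effective_strength <- function(loops, cond, multiplier) {
  s <- loops$strength
  if (cond$genotype == "mut")
    s[loops$zf1_dependent] <- pmax(1, s[loops$zf1_dependent] * multiplier)
  s[!loop_active(loops, cond$cell)] <- 1
  s
}

# Per-chromosome stratified expected weights (list indexed by d+1) with loop
# factors applied; returns list(W = list of vectors, total = Z).
lambda_strata <- function(cfg, truth, chrom, cond) {
  genome <- truth$genome
  n <- genome$n_bins[[chrom]]
  lab <- truth$compartments[chrom, on = "chrom"]$label
  tad <- truth$tads[chrom, on = "chrom"]$tad
  a1 <- cfg$decay_exponent; d0 <- cfg$decay_offset
  cs <- cfg$compartment_strength; ts <- cfg$tad_strength
  W <- vector("list", n)
  tot <- 0
  for (d in 0:(n - 1L)) {
    a <- 1:(n - d)
    w <- (d0 + d)^(-a1) * cs^(lab[a] * lab[a + d])
    if (ts != 1) w <- w * ifelse(tad[a] == tad[a + d], ts, 1)
    W[[d + 1L]] <- w
    tot <- tot + sum(w)
  }
  loops <- truth$loops[chrom, on = "chrom", nomatch = NULL]
  if (nrow(loops)) {
    s_eff <- effective_strength(loops, cond, cfg$mutant_multiplier)
    for (li in seq_len(nrow(loops))) {
      s <- s_eff[li]
      if (s == 1) next
      for (da in -1:1) for (db in -1:1) {
        a <- loops$bin_i[li] + da + 1L  # 1-based row in stratum vector
        b <- loops$bin_j[li] + db
        d <- b - (a - 1L)
        if (d < 2 || a < 1 || b >= n) next
        wgt <- if (da == 0 && db == 0) 1 else 0.5
        old <- W[[d + 1L]][a]
        W[[d + 1L]][a] <- old * s^wgt
        tot <- tot + W[[d + 1L]][a] - old
      }
    }
  }
  list(W = W, total = tot)
}

#' Simulate a contact map for one condition
#'
#' Draws independent Poisson counts around the planted expected intensities
#' (see [sim_config()] for the model).  Identical `(config, condition,
#' seed)` give byte-identical output.
#'
#' @param config a [sim_config()].
#' @param condition one of `"ESC-WT"`, `"ESC-mut"`, `"NPC-WT"`, `"NPC-mut"`.
#' @param seed integer seed for the Poisson draws (independent of the
#'   ground-truth realization, which is governed by `config$seed`).
#' @param truth optional pre-computed [realize_truth()] result (saves time
#'   when simulating several conditions from one truth).
#' @return list with elements `map` (a [contact_map()]) and `truth`
#'   (the [realize_truth()] object).
#' @export
simulate_contacts <- function(config, condition, seed = 1L, truth = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  validate_sim_config(config)
  cond <- parse_condition(condition)
  if (is.null(truth)) truth <- realize_truth(config)
  genome <- truth$genome
  trip <- with_seed(seed, {
    out <- list()
    for (cn in genome$chrom) {
      n <- genome$n_bins[[cn]]
      ls <- lambda_strata(config, truth, cn, cond)
      scale <- config$depth / ls$total
      chunk <- vector("list", n)
      for (d in 0:(n - 1L)) {
        lam <- ls$W[[d + 1L]] * scale
        cnt <- stats::rpois(length(lam), lam)
        nz <- which(cnt > 0L)
        if (length(nz))
          chunk[[d + 1L]] <- data.table::data.table(
            chrom = cn, bin_i = nz - 1L, bin_j = nz - 1L + d, count = cnt[nz])
      }
      out[[cn]] <- data.table::rbindlist(chunk)
    }
    data.table::rbindlist(out)
  })
  list(map = contact_map(genome, trip), truth = truth)
}

#' Expected contact intensity at given pixels
#'
#' Evaluates the generator's expected intensity `lambda` for requested bin
#' pairs under a condition: the planted oracle for enrichment checks.
#'
#' @param truth a [realize_truth()] object.
#' @param condition condition label as in [simulate_contacts()].
#' @param pixels data.frame with columns `chrom`, `bin_i`, `bin_j`.
#' @return numeric vector of expected counts.
#' @export
expected_lambda <- function(truth, condition, pixels) {
  stopifnot(inherits(truth, "GroundTruth"))
  cfg <- truth$config
  cond <- parse_condition(condition)
  px <- data.table::as.data.table(pixels)
  out <- numeric(nrow(px))
  for (cn in unique(px$chrom)) {
    ls <- lambda_strata(cfg, truth, cn, cond)
    scale <- cfg$depth / ls$total
    idx <- which(px$chrom == cn)
    for (k in idx) {
      d <- abs(px$bin_j[k] - px$bin_i[k])
      a <- min(px$bin_i[k], px$bin_j[k]) + 1L
      out[k] <- ls$W[[d + 1L]][a] * scale
    }
  }
  out
}

#' Simulate CTCF/cohesin peak intervals with per-sample counts
#'
#' Places a 300-bp peak at the centre of every distinct planted loop anchor
#' bin (binding is cell-type invariant) plus `n_background_peaks` random
#' background sites per chromosome, then draws NB counts for WT and mutant
#' ChIP replicates.  Counts are condition-invariant unless a per-peak
#' `peak_log2fc` is configured (applied in the mutant).
#'
#' @inheritParams simulate_contacts
#' @param cell `"ESC"` or `"NPC"` (peak placement itself is invariant; the
#'   label is recorded on the output).
#' @return list with `peaks` (data.table: `chrom`, `start`, `end`, `name`,
#'   `type` anchor/background, `loop_id`) and `counts` (peaks x samples
#'   integer matrix with WT and mut replicate columns).
#' @export
simulate_peaks <- function(config, cell = "ESC", seed = 1L, truth = NULL) {
  stopifnot(inherits(config, "SimConfig"), cell %in% c("ESC", "NPC"))
  if (is.null(truth)) truth <- realize_truth(config)
  genome <- truth$genome
  bs <- genome$bin_size
  anchors <- unique(rbind(truth$loops[, .(chrom, bin = bin_i)],
                          truth$loops[, .(chrom, bin = bin_j)]))
  data.table::setkey(anchors, chrom, bin)
  with_seed(seed, {
    centre <- anchors$bin * bs + bs %/% 2
    pk <- anchors[, .(chrom, start = centre - 150, end = centre + 150)]
    pk[, `:=`(type = "anchor")]
    nbk <- config$n_background_peaks
    if (nbk > 0) {
      bg <- list()
      for (cn in genome$chrom) {
        used <- anchors[cn, on = "chrom", nomatch = NULL]$bin
        free <- setdiff(0:(genome$n_bins[[cn]] - 1L), used)
        b <- sample(free, min(nbk, length(free)))
        cc <- b * bs + bs %/% 2
        bg[[cn]] <- data.table::data.table(chrom = cn, start = cc - 150,
                                           end = cc + 150, type = "background")
      }
      pk <- rbind(pk, data.table::rbindlist(bg))
    }
    pk[, name := sprintf("peak_%04d", seq_len(.N))]
    lfc <- if (is.null(config$peak_log2fc)) rep(0, nrow(pk)) else
      rep_len(config$peak_log2fc, nrow(pk))
    nr <- config$replicates$chip
    mu_wt <- rep(config$peak_base_mean, nrow(pk))
    mu_mut <- mu_wt * 2^lfc
    draw <- function(mu) {
      if (config$peak_dispersion == 0) stats::rpois(length(mu), mu) else
        stats::rnbinom(length(mu), mu = mu, size = 1 / config$peak_dispersion)
    }
    counts <- cbind(
      matrix(unlist(lapply(seq_len(nr), function(r) draw(mu_wt))), ncol = nr,
             dimnames = list(pk$name, sprintf("%s_WT_%d", cell, seq_len(nr)))),
      matrix(unlist(lapply(seq_len(nr), function(r) draw(mu_mut))), ncol = nr,
             dimnames = list(pk$name, sprintf("%s_mut_%d", cell, seq_len(nr)))))
    list(peaks = pk[], counts = counts)
  })
}

#' Simulate an expression count matrix
#'
#' NB counts with mean `base_mean * 2^(lfc x condition indicators) *
#' size_factor` and gene-level dispersion (Poisson when dispersion is 0).
#' Size factors are drawn log-uniform in `size_factor_range`.
#'
#' @inheritParams simulate_contacts
#' @param conditions character vector of condition labels to simulate.
#' @param replicates replicates per condition (>= 2).
#' @return list with `counts` (genes x samples integer matrix),
#'   `samples` (data.table `sample`, `condition`) and `size_factors`
#'   (the planted truth).
#' @export
simulate_expression <- function(config, conditions = sim_conditions(),
                                replicates = NULL, seed = 1L, truth = NULL) {
  stopifnot(inherits(config, "SimConfig"))
  if (is.null(replicates)) replicates <- config$replicates$expression
  if (replicates < 2) stop("need >= 2 replicates per condition")
  if (is.null(truth)) truth <- realize_truth(config)
  genes <- truth$genes
  with_seed(seed, {
    samples <- data.table::data.table(
      condition = rep(conditions, each = replicates))
    samples[, sample := sprintf("%s_r%d", condition, seq_len(.N)), by = condition]
    sf <- exp(stats::runif(nrow(samples), log(config$size_factor_range[1]),
                           log(config$size_factor_range[2])))
    names(sf) <- samples$sample
    counts <- matrix(0L, nrow(genes), nrow(samples),
                     dimnames = list(genes$id, samples$sample))
    for (k in seq_len(nrow(samples))) {
      cond <- parse_condition(samples$condition[k])
      lfc <- (cond$cell == "NPC") * genes$lfc_cell +
        (cond$genotype == "mut") *
          (if (cond$cell == "ESC") genes$lfc_mut_esc else genes$lfc_mut_npc)
      mu <- genes$base_mean * 2^lfc * sf[k]
      counts[, k] <- ifelse(genes$dispersion == 0,
                            stats::rpois(nrow(genes), mu),
                            stats::rnbinom(nrow(genes), mu = mu,
                                           size = 1 / pmax(genes$dispersion, 1e-12)))
    }
    list(counts = counts, samples = samples[], size_factors = sf)
  })
}

#' Simulate replicated CLIP crosslink tracks plus a control
#'
#' Per replicate, crosslink events fall as per-nucleotide Poisson draws at
#' the gene's condition-specific `clip_rate` within gene bodies (on the
#' gene's strand), plus a uniform genome-wide background on both strands.
#' The non-crosslinked control carries background only.
#'
#' @inheritParams simulate_contacts
#' @param cell `"ESC"` or `"NPC"`: selects `clip_rate_esc`/`clip_rate_npc`.
#' @param replicates number of crosslinked replicates (>= 3).
#' @return list with `replicates` (list of crosslink tracks: data.tables
#'   `chrom`, `pos`, `strand`, `count`, with attributes `genome`,
#'   `replicate`, `condition`, `is_control`) and `control` (one track).
#' @export
simulate_clip <- function(config, cell = "NPC", replicates = NULL, seed = 1L,
                          truth = NULL) {
  stopifnot(inherits(config, "SimConfig"), cell %in% c("ESC", "NPC"))
  if (is.null(replicates)) replicates <- config$replicates$clip
  if (replicates < 3) stop("need >= 3 CLIP replicates")
  if (is.null(truth)) truth <- realize_truth(config)
  genome <- truth$genome
  genes <- truth$genes
  rate <- if (cell == "ESC") genes$clip_rate_esc else genes$clip_rate_npc
  with_seed(seed, {
    one_track <- function(include_genes, bg_rate) {
      ev <- list()
      if (include_genes) {
        pos <- which(rate > 0)
        for (gi in pos) {
          lo <- min(genes$tss[gi], genes$tes[gi])
          hi <- max(genes$tss[gi], genes$tes[gi])
          nev <- stats::rpois(1, rate[gi] * (hi - lo))
          if (nev > 0)
            ev[[length(ev) + 1]] <- data.table::data.table(
              chrom = genes$chrom[gi],
              pos = lo + sample.int(hi - lo, nev, replace = TRUE) - 1L,
              strand = genes$strand[gi])
        }
      }
      # uniform background on both strands
      for (cn in genome$chrom) {
        len <- unname(genome$length[[cn]])
        nbg <- stats::rpois(1, 2 * len * bg_rate)
        if (nbg > 0)
          ev[[length(ev) + 1]] <- data.table::data.table(
            chrom = cn, pos = sample.int(len, nbg, replace = TRUE) - 1L,
            strand = sample(c("+", "-"), nbg, replace = TRUE))
      }
      dt <- if (length(ev)) data.table::rbindlist(ev) else
        data.table::data.table(chrom = character(), pos = integer(),
                               strand = character())
      dt <- dt[, .(count = .N), by = .(chrom, pos, strand)]
      data.table::setkey(dt, chrom, strand, pos)
      dt
    }
    reps <- lapply(seq_len(replicates), function(r) {
      tr <- one_track(TRUE, config$clip$background)
      crosslink_track(tr, genome, replicate = r, condition = cell,
                      is_control = FALSE)
    })
    ctrl <- crosslink_track(one_track(FALSE, config$clip$control_rate), genome,
                            replicate = 0L, condition = cell, is_control = TRUE)
    list(replicates = reps, control = ctrl)
  })
}

#' Write the planted ground truth to a directory of plain-text files
#'
#' Emits the manifest consumed by tests and downstream tools: planted loops
#' as BEDPE, compartment labels and TAD boundaries as TSV, genes as the
#' 5-column gene table.
#'
#' @param truth a [realize_truth()] object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "GroundTruth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  bs <- truth$genome$bin_size
  lp <- truth$loops
  bedpe <- data.table::data.table(
    chrom1 = lp$chrom, start1 = lp$bin_i * bs, end1 = (lp$bin_i + 1) * bs,
    chrom2 = lp$chrom, start2 = lp$bin_j * bs, end2 = (lp$bin_j + 1) * bs,
    name = lp$id, score = lp$strength, strand1 = ".", strand2 = ".",
    zf1_dependent = lp$zf1_dependent, cell_specific = lp$cell_specific)
  data.table::fwrite(bedpe, file.path(dir, "planted_loops.bedpe"), sep = "\t")
  data.table::fwrite(truth$compartments, file.path(dir, "compartments.tsv"), sep = "\t")
  data.table::fwrite(truth$tad_boundaries, file.path(dir, "tad_boundaries.tsv"), sep = "\t")
  data.table::fwrite(truth$genes, file.path(dir, "genes.tsv"), sep = "\t")
  invisible(dir)
}
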