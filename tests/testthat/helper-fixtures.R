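# Shared fixtures, built lazily once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# evict large cached fixtures once no later test needs them (keeps the
# whole-suite peak footprint within a small-memory container)
drop_fixtures <- function(...) {
  nm <- intersect(c(...), ls(envir = .fixture_env))
  if (length(nm)) rm(list = nm, envir = .fixture_env)
  invisible(gc(FALSE))
}

# a tiny two-chromosome genome for coordinate arithmetic tests
tiny_genome <- function() binned_genome(c("chrA", "chrB"), c(95000, 60000),
                                        bin_size = 10000)

# dense constant-background map on one chromosome: every pair at separation
# >= 1 carries `base` counts, plus optional hot pixels.  The analytic decay
# is flat, so O/E is ~1 away from the hot pixels.
flat_map <- function(n = 120L, base = 4L, hot = NULL, chrom = "chrF",
                     bin_size = 5000L) {
  g <- binned_genome(chrom, n * bin_size, bin_size)
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  dt <- data.table::data.table(chrom = chrom, bin_i = ij[, 1] - 1L,
                               bin_j = ij[, 2] - 1L, count = base)
  if (!is.null(hot)) {
    for (r in seq_len(nrow(hot))) {
      sel <- dt$bin_i == hot$bin_i[r] & dt$bin_j == hot$bin_j[r]
      dt$count[sel] <- hot$count[r]
    }
  }
  contact_map(g, dt)
}

# mid-scale single-chromosome simulation config with explicit planted loops
mid_loops <- function() data.table::data.table(
  chrom = "chrT",
  bin_i = c(220L, 420L, 620L, 240L, 460L, 680L,
            210L, 350L, 500L, 600L, 750L, 150L),
  bin_j = c(380L, 590L, 800L, 430L, 640L, 830L,
            280L, 430L, 570L, 700L, 820L, 250L),
  strength = c(8, 8, 8, 8, 9, 8, 7, 7, 7, 7, 7, 7),
  zf1_dependent = rep(c(TRUE, FALSE), each = 6L),
  cell_specific = c("NPC", "NPC", "NPC", "ESC", "ESC", "common",
                    "common", "common", "ESC", "NPC", "common", "common"))

mid_cfg <- function() fixture("mid_cfg", function() sim_config(
  seed = 11L, chromosomes = c(chrT = 5e6), bin_size = 5000, depth = 2e6,
  compartment_block = 60, tad_size_range = c(20L, 40L),
  loops = mid_loops()))

mid_truth <- function() fixture("mid_truth", function()
  realize_truth(mid_cfg()))

# the default-scale study configuration (generator defaults untouched)
default_cfg <- function() fixture("default_cfg", function() sim_config())

default_truth <- function() fixture("default_truth", function()
  realize_truth(default_cfg()))

default_wt_map <- function() fixture("default_wt_map", function()
  simulate_contacts(default_cfg(), "ESC-WT", seed = 101L,
                    truth = default_truth())$map)

default_wt_profile <- function() fixture("default_wt_profile", function()
  expected_by_distance(default_wt_map()))

default_wt_calls <- function() fixture("default_wt_calls", function()
  call_loops(default_wt_map(), default_wt_profile(), fdr = 0.01,
             condition = "ESC-WT"))

# tiny pipeline config (fast end-to-end runs)
write_tiny_config <- function(path, seed = 3L, mutant_multiplier = 0.15) {
  yaml::write_yaml(list(
    seed = seed,
    genome = list(chromosomes = list(chrA = 5e6, chrB = 4e6),
                  bin_size = 5000L),
    simulate = list(depth = 1.5e6, compartment_block = 60L,
                    tad_size_range = c(20L, 40L),
                    mutant_multiplier = mutant_multiplier,
                    n_background_peaks = 60L)), path)
  path
}
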