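# Shared fixtures, built lazily once per test run and cached, so expensive
# objects (burned-in populations) are reused across test files.

.fx <- new.env(parent = emptyenv())

# small, fast default landscape (64x64, unit SD)
fx_landscape <- function(seed = 3, l_e = 0.1, resolution = 64) {
  key <- sprintf("land_%s_%s_%s", seed, l_e, resolution)
  if (is.null(.fx[[key]]))
    .fx[[key]] <- generate_landscape(landscape_params(
      seed = seed, l_e = l_e, resolution = resolution))
  .fx[[key]]
}

# wrap an arbitrary matrix as an env_landscape (for printed toy grids;
# bypasses generator validation so tiny grids are allowed)
fx_landscape_from_matrix <- function(m) {
  params <- structure(list(mu_e = mean(m), sigma_e = stats::sd(m), l_e = 0.1,
                           amplitude_a = 1, slope_s = 0, curvature_c = 0,
                           resolution = nrow(m), seed = 0L),
                      class = "landscape_params")
  structure(list(grid = m, params = params, gearys_c = NA_real_),
            class = "env_landscape")
}

# wrap a binary matrix as a loss_scenario (for constructed loss patterns)
fx_scenario_from_matrix <- function(m, l_hl = 0.1, p_l = mean(m)) {
  structure(list(loss_grid = matrix(as.integer(m), nrow(m), ncol(m)),
                 l_hl = l_hl, p_l = p_l, seed = 0L),
            class = "loss_scenario")
}

# small config for fast dynamics tests: K stays at the calibrated 500 (the
# population is not demographically viable far below it) and the burn-in is
# shortened, which preserves local adaptation on the 64x64 fixture landscape
fx_cfg <- function(...) {
  args <- utils::modifyList(list(K = 500, burn_in = 300L), list(...))
  do.call(sim_config, args)
}

# a modest burned-in population on a 64x64 landscape, cached
fx_burnin <- function() {
  if (is.null(.fx$burnin)) {
    .fx$burnin <- run_burn_in(fx_landscape(), fx_cfg(), seed = 11)
  }
  .fx$burnin
}

# construct a minimal sim_state by hand (for genome/phenotype tests);
# alleles: data.frame(effect, group, site); hapA/hapB: lists of 0-based
# allele-id vectors
fx_state <- function(x, y, hapA, hapB, alleles = NULL, age = NULL) {
  n <- length(x)
  if (is.null(alleles))
    alleles <- data.frame(effect = numeric(0), group = integer(0),
                          site = integer(0))
  phen <- vapply(seq_len(n), function(i)
    sum(alleles$effect[hapA[[i]] + 1L]) + sum(alleles$effect[hapB[[i]] + 1L]),
    numeric(1))
  structure(list(
    x = x, y = y, age = if (is.null(age)) integer(n) else as.integer(age),
    id = seq_len(n), phen = phen, hapA = hapA, hapB = hapB,
    allele_effect = alleles$effect, allele_group = as.integer(alleles$group),
    allele_site = as.integer(alleles$site),
    next_id = n + 1L, generation = 0L), class = "sim_state")
}
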