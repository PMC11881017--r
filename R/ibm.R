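#' Simulation configuration
#'
#' All parameters of the individual-based model. Defaults are the package's
#' calibrated stand-ins chosen so that (a) burn-in populations never go
#' extinct and (b) persistence under a central habitat-loss-plus-warming
#' scenario is intermediate (neither 0 nor 1), so landscape effects are
#' identifiable.
#'
#' @param K Landscape-wide carrying capacity (individuals). Enters fitness
#'   through the local competition term, not as a hard cap.
#' @param sigma_p Perception/interaction distance (landscape units): SD of
#'   the Gaussian competition kernel, mate-search and movement radius scale.
#'   Interactions are cut off at `3 * sigma_p`.
#' @param sigma_f SD of the Gaussian phenotype-environment matching function
#'   (environment units). Smaller values mean stronger stabilizing selection.
#' @param sigma_qtl SD of QTL mutational effect sizes (phenotype units).
#' @param mu_rate Per-site mutation rate.
#' @param p_qtl Scaling quantity on the mutation rate (the product
#'   `mu_rate * p_qtl` is the per-site QTL mutation rate).
#' @param lambda_0 Mean offspring per reproduction event (Poisson mean).
#' @param max_age Maximum individual age in generations (hard cap, 10).
#' @param burn_in Initialization generations (local adaptation; mutations
#'   occur only during this phase).
#' @param delta_e Total environmental increase of the warming ramp.
#' @param change_duration Generations of environmental change (100).
#' @param post_change Generations simulated after the change ends (100).
#' @param n_linkage_groups Total linkage groups (20; the second half is
#'   reserved for neutral variation and carries no simulated mutations).
#' @param n_qtl_groups QTL-bearing linkage groups actually simulated (10).
#' @param sites_per_group Sites per linkage group (50,000).
#' @param recomb_rate Per-site recombination rate within a linkage group;
#'   linkage groups assort freely.
#' @param sigma_b0 Selection-ramp start value (`sigma_b` at generation 0).
#' @param habitat_choice How a movement candidate is evaluated: `"fitness"`
#'   (full product expression, default) or `"match"` (phenotype-environment
#'   matching only).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(K = 1000, sigma_p = 0.02, sigma_f = 0.4,
                       sigma_qtl = 0.1, mu_rate = 1e-7, p_qtl = 1,
                       lambda_0 = 0.45, max_age = 10L, burn_in = 10000L,
                       delta_e = 3, change_duration = 100L,
                       post_change = 100L, n_linkage_groups = 20L,
                       n_qtl_groups = 10L, sites_per_group = 50000L,
                       recomb_rate = 1e-8, sigma_b0 = 0.1,
                       habitat_choice = c("fitness", "match")) {
  habitat_choice <- match.arg(habitat_choice)
  if (sigma_p <= 0) stop("`sigma_p` must be positive", call. = FALSE)
  if (sigma_f <= 0) stop("`sigma_f` must be positive", call. = FALSE)
  stopifnot(K > 0, sigma_qtl >= 0, mu_rate >= 0, p_qtl >= 0, lambda_0 >= 0,
            burn_in >= 1, change_duration >= 1, post_change >= 0,
            recomb_rate >= 0, sigma_b0 > 0, sigma_b0 <= 1)
  structure(list(
    K = K, sigma_p = sigma_p, sigma_f = sigma_f, sigma_qtl = sigma_qtl,
    mu_rate = mu_rate, p_qtl = p_qtl, lambda_0 = lambda_0,
    max_age = as.integer(max_age), burn_in = as.integer(burn_in),
    delta_e = delta_e, change_duration = as.integer(change_duration),
    post_change = as.integer(post_change),
    n_linkage_groups = as.integer(n_linkage_groups),
    n_qtl_groups = as.integer(n_qtl_groups),
    sites_per_group = as.integer(sites_per_group),
    recomb_rate = recomb_rate, sigma_b0 = sigma_b0,
    habitat_choice_full = habitat_choice == "fitness"
  ), class = "sim_config")
}

#' Gaussian competition kernel
#'
#' Strength of competition between two individuals at distance `d`:
#' `exp(-d^2 / (2 sigma_p^2))` when `d < 3 sigma_p`, and 0 (no interaction)
#' beyond the cutoff.
#'
#' @param d Distance(s), non-negative.
#' @param sigma_p Perception distance (positive).
#' @return Competition strength in `[0, 1]`.
#' @export
competition_kernel <- function(d, sigma_p) {
  if (sigma_p <= 0) stop("`sigma_p` must be positive", call. = FALSE)
  ifelse(d < 3 * sigma_p, exp(-d^2 / (2 * sigma_p^2)), 0)
}

#' Total competition felt by each individual
#'
#' Sum of the competition kernel over all other individuals within
#' `3 sigma_p` (torus distances). `method = "indexed"` uses the cell-list
#' spatial index of the simulation core; `"naive"` is the all-pairs
#' reference implementation.
#'
#' @param x,y Positions in `[0, 1)`.
#' @param sigma_p Perception distance.
#' @param method `"indexed"` (default) or `"naive"`.
#' @return Numeric vector of `C_i` values.
#' @export
total_competition <- function(x, y, sigma_p, method = c("indexed", "naive")) {
  method <- match.arg(method)
  if (method == "indexed") return(total_competition_cpp(x, y, sigma_p))
  n <- length(x)
  dx <- abs(outer(x, x, "-")); dx <- pmin(dx, 1 - dx)
  dy <- abs(outer(y, y, "-")); dy <- pmin(dy, 1 - dy)
  d <- sqrt(dx^2 + dy^2)
  ck <- competition_kernel(d, sigma_p)
  diag(ck) <- 0
  rowSums(ck)
}

#' Selection-ramp schedule for sigma_b
#'
#' During the burn-in, the weight `sigma_b` placed on phenotype-environment
#' matching ramps linearly from `sigma_b0` at generation 0 to 1 at
#' generation `burn_in`, and holds 1 thereafter. The ramp is scaled to the
#' configured burn-in length, so shortened burn-ins keep the schedule shape.
#'
#' @param generation Generation(s), non-negative.
#' @param burn_in Burn-in length in generations.
#' @param sigma_b0 Start value (default 0.1).
#' @return `sigma_b` value(s) in `(0, 1]`.
#' @export
sigma_b_schedule <- function(generation, burn_in, sigma_b0 = 0.1) {
  pmin(1, sigma_b0 + (1 - sigma_b0) * generation / burn_in)
}

#' Phenotype-environment matching component of fitness
#'
#' The Gaussian factor `exp(-((P - e) * sigma_b)^2 / (2 sigma_f^2))`, with
#' maximum value 1 at a perfect phenotype-environment match. `sigma_b`
#' scales the phenotypic deviation, so small `sigma_b` weakens selection
#' and `sigma_b = 1` recovers the plain Gaussian.
#'
#' @param phenotype Individual phenotype `P_i`.
#' @param env_value Environmental value `e` at the individual's position.
#' @param sigma_b Selection-ramp value in `(0, 1]`.
#' @param sigma_f Matching-function SD (positive).
#' @return Matching factor in `(0, 1]`.
#' @export
match_component <- function(phenotype, env_value, sigma_b, sigma_f) {
  if (any(sigma_f <= 0)) stop("`sigma_f` must be positive", call. = FALSE)
  dev <- (phenotype - env_value) * sigma_b
  exp(-dev^2 / (2 * sigma_f^2))
}

#' Survival probability (product fitness expression)
#'
#' `w_i = min(1, (2 pi sigma_p^2 K / C_i) * match)`: the competition factor
#' boosts fitness at low local density and penalizes crowding above the
#' local carrying capacity; the matching factor is [match_component()].
#' `C_i = 0` (no neighbours) gives competition factor 1 before clamping;
#' positions in destroyed habitat (signalled by `env_value = NA`) give 0.
#'
#' @param phenotype,env_value,sigma_b As in [match_component()];
#'   `env_value = NA` marks destroyed habitat.
#' @param C_i Total competition (non-negative).
#' @param cfg A [sim_config()].
#' @return Survival probability in `[0, 1]`.
#' @export
fitness_weight <- function(phenotype, env_value, C_i, cfg, sigma_b = 1) {
  comp <- ifelse(C_i > 0, 2 * pi * cfg$sigma_p^2 * cfg$K / C_i, 1)
  w <- pmin(1, comp * match_component(phenotype, env_value, sigma_b, cfg$sigma_f))
  ifelse(is.na(env_value), 0, w)
}

#' Initial population state
#'
#' `K` individuals at uniform random positions with empty genomes
#' (phenotype 0) and age 0, at generation 0.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (optional; when `NULL` the current RNG stream
#'   is used, as inside [run_burn_in()]).
#' @return An object of class `sim_state`.
#' @export
new_population <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(cfg$K)
  structure(list(
    x = stats::runif(n), y = stats::runif(n),
    age = integer(n), id = seq_len(n), phen = numeric(n),
    hapA = rep(list(integer(0)), n), hapB = rep(list(integer(0)), n),
    allele_effect = numeric(0), allele_group = integer(0),
    allele_site = integer(0), next_id = n + 1L, generation = 0L
  ), class = "sim_state")
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> generation %d | %d individuals | %d segregating alleles\n",
              x$generation, length(x$x), n_segregating(x)))
  invisible(x)
}

#' Number of distinct segregating QTL alleles in a population
#'
#' @param state A `sim_state`.
#' @return Integer count.
#' @export
n_segregating <- function(state) {
  length(unique(c(unlist(state$hapA, use.names = FALSE),
                  unlist(state$hapB, use.names = FALSE))))
}

#' Recompute an individual's phenotype from its genome
#'
#' Sum of the effect sizes of all QTL alleles on both haplotypes (a
#' homozygous allele counts twice: per-copy additivity). Used to verify the
#' cached phenotypes carried by the simulation.
#'
#' @param state A `sim_state`.
#' @param i Individual index (vectorized).
#' @return Numeric phenotype(s).
#' @export
phenotype_of <- function(state, i = seq_along(state$x)) {
  vapply(i, function(k) {
    sum(state$allele_effect[state$hapA[[k]] + 1L]) +
      sum(state$allele_effect[state$hapB[[k]] + 1L])
  }, numeric(1))
}

#' Nearest-neighbour mate selection
#'
#' The strictly nearest other individual, provided it is within
#' `3 sigma_p` (torus distance); exact distance ties are broken by lowest
#' individual id. Returns `NA` when no individual is in range, in which
#' case the focal individual does not reproduce that generation.
#'
#' @param state A `sim_state`.
#' @param i Focal individual index.
#' @param sigma_p Perception distance.
#' @return Index of the selected mate, or `NA`.
#' @export
select_mate <- function(state, i, sigma_p) {
  j <- nearest_neighbor_cpp(state$x, state$y, state$id, sigma_p)[i]
  if (is.na(j)) NA_integer_ else j
}

# internal: run the compiled core for n_gen generations
ibm_run <- function(state, landscape, cfg, n_gen, scenario = NULL,
                    schedule = NULL) {
  loss <- if (is.null(scenario)) matrix(0L, 0, 0) else scenario$loss_grid
  if (is.null(schedule)) {
    res <- ibm_run_cpp(landscape$grid, loss, unclass(cfg), unclass(state),
                       n_gen, 0, 0L, 0L)
  } else {
    res <- ibm_run_cpp(landscape$grid, loss, unclass(cfg), unclass(state),
                       n_gen, schedule$delta_e, schedule$duration,
                       schedule$start_gen)
  }
  res$census <- as.data.frame(res$census)
  res
}

#' Advance the simulation by whole generations
#'
#' One generation applies, in fixed order: (1) reproduction (nearest-
#' neighbour mating, Poisson offspring at parent 1's position),
#' (2) habitat choice for every individual including newborns,
#' (3) viability selection (Bernoulli survival with probability `w_i`),
#' (4) ageing with removal above the age cap, (5) schedule updates.
#' Extinction is absorbing. Identical seeds give identical trajectories.
#'
#' @param state A `sim_state`.
#' @param landscape An `env_landscape`.
#' @param cfg A [sim_config()].
#' @param n_gen Number of generations to advance (default 1).
#' @param scenario Optional `loss_scenario` (destroyed cells are unsuitable).
#' @param schedule Optional [warming_schedule()].
#' @param seed Optional seed set before stepping.
#' @return List with `state` (advanced) and `census` (one row per
#'   generation: population size, segregating alleles, phenotype mean and
#'   variance, mean per-individual displacement, maximum age).
#' @export
step_generation <- function(state, landscape, cfg, n_gen = 1L,
                            scenario = NULL, schedule = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ibm_run(state, landscape, cfg, n_gen, scenario, schedule)
}

#' Burn-in: local adaptation on the intact landscape
#'
#' Evolves an initial population ([new_population()]) for `cfg$burn_in`
#' generations with the selection ramp active and de novo QTL mutation on.
#' By the end, `sigma_b = 1` and the population is locally adapted to the
#' environmental gradient (phenotypes track local environmental values).
#'
#' @param landscape An `env_landscape`.
#' @param cfg A [sim_config()].
#' @param seed Integer seed governing the whole burn-in.
#' @return List with `state` (the burned-in `sim_state`) and `census`.
#' @export
run_burn_in <- function(landscape, cfg, seed = 1L) {
  set.seed(seed)
  state <- new_population(cfg)
  res <- ibm_run(state, landscape, cfg, cfg$burn_in)
  if (length(res$state$x) == 0)
    stop("population went extinct during burn-in; the configuration is mis-calibrated",
         call. = FALSE)
  res
}

#' Apply habitat loss to a population in a single generation
#'
#' Removes every individual whose position falls on a destroyed cell; their
#' genotypes leave the population with them. Destroyed cells remain
#' unsuitable for the rest of the simulation (fitness 0 there, and habitat
#' choice never accepts them).
#'
#' @param state A `sim_state` (normally at burn-in end).
#' @param scenario A `loss_scenario`.
#' @return The pruned `sim_state` (possibly empty).
#' @export
apply_habitat_loss <- function(state, scenario) {
  R <- nrow(scenario$loss_grid)
  ix <- floor((state$x %% 1) * R) + 1L
  iy <- floor((state$y %% 1) * R) + 1L
  keep <- scenario$loss_grid[cbind(ix, iy)] == 0L
  out <- state
  for (f in c("x", "y", "age", "id", "phen")) out[[f]] <- state[[f]][keep]
  out$hapA <- state$hapA[keep]
  out$hapB <- state$hapB[keep]
  out
}

#' Run a habitat-loss + warming scenario from a burned-in state
#'
#' Habitat loss is applied in a single generation; in that same generation
#' the landscape-wide environmental value begins its linear increase
#' (`delta_e` over `cfg$change_duration` generations), after which the
#' population is followed for `cfg$post_change` further generations. A
#' per-generation census is recorded, together with the pre-loss census
#' used as the baseline for the outcome ratios.
#'
#' @param burned A burned-in `sim_state` (from [run_burn_in()]).
#' @param landscape The `env_landscape` the state was burned in on.
#' @param scenario A `loss_scenario`.
#' @param cfg A [sim_config()].
#' @param delta_e Warming amount (defaults to `cfg$delta_e`; use 0 for the
#'   no-change control arm).
#' @param seed Integer seed for the post-loss dynamics.
#' @return An object of class `sim_trajectory`: list with `census`
#'   (post-loss, one row per generation), `pre` (pre-loss baseline: size,
#'   segregating alleles, phenotype mean/variance), `delta_e`, and the
#'   post-loss generation span.
#' @export
run_scenario <- function(burned, landscape, scenario, cfg,
                         delta_e = cfg$delta_e, seed = 1L) {
  pre <- list(
    n = length(burned$x),
    n_alleles = n_segregating(burned),
    mean_phenotype = if (length(burned$x)) mean(burned$phen) else NA_real_,
    var_phenotype = if (length(burned$x) > 1) stats::var(burned$phen) else NA_real_
  )
  set.seed(seed)
  state <- apply_habitat_loss(burned, scenario)
  sched <- warming_schedule(delta_e, cfg$change_duration,
                            start_gen = state$generation)
  n_gen <- cfg$change_duration + cfg$post_change
  res <- ibm_run(state, landscape, cfg, n_gen, scenario, sched)
  census <- res$census
  census$post_gen <- seq_len(nrow(census))
  structure(list(census = census, pre = pre, delta_e = delta_e,
                 n_post = n_gen, state = res$state),
            class = "sim_trajectory")
}
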