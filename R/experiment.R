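#' Study design: sizes, parameters and seeding for a full experiment
#'
#' Bundles everything a design run needs. The default profile is
#' desk-scale; `profile = "full"` switches to the cluster-scale design
#' (50 landscapes, 50 scenarios per property, 100 replicates, 10,000
#' generation burn-in, 100,000 candidate scenarios), which is provided as
#' a recipe and is far beyond a single workstation.
#'
#' Every run's seed is derived from `(master_seed, landscape, scenario,
#' replicate, arm)` with [derive_seed()], so any single cell of the design
#' can be reproduced in isolation.
#'
#' @param n_landscapes Number of environmental landscapes.
#' @param n_scenarios Habitat-loss scenarios per landscape property.
#' @param n_replicates Replicate populations per scenario.
#' @param n_candidates Candidate-pool size per landscape for weighted
#'   density sampling.
#' @param cfg A [sim_config()]; the desk profile shortens the burn-in and
#'   reduces K.
#' @param properties Landscape properties under study.
#' @param delta_e_arms Warming amounts simulated for every scenario
#'   (default: with and without environmental change).
#' @param l_e Environmental autocorrelation length of generated landscapes.
#' @param resolution Grid resolution.
#' @param l_hl_range Range of loss autocorrelation lengths in the pool.
#' @param p_l Destroyed fraction (study-wide 2/3).
#' @param share_burn_in If `TRUE` (default) one burn-in per (landscape,
#'   replicate) is shared across that landscape's scenarios and arms;
#'   if `FALSE` every scenario gets an independent burn-in.
#' @param master_seed Master seed of the whole design.
#' @param profile `"desk"` (default) or `"full"`.
#' @return An object of class `study_design`.
#' @export
study_design <- function(n_landscapes = 5L, n_scenarios = 15L,
                         n_replicates = 20L, n_candidates = 2000L,
                         cfg = sim_config(K = 500, burn_in = 1500L),
                         properties = c("delta_Be", "delta_mu_e", "l_hl"),
                         delta_e_arms = c(3, 0), l_e = 0.1,
                         resolution = 128L, l_hl_range = c(0.01, 0.25),
                         p_l = 2 / 3, share_burn_in = TRUE,
                         master_seed = 1L, profile = c("desk", "full")) {
  profile <- match.arg(profile)
  if (profile == "full") {
    n_landscapes <- 50L; n_scenarios <- 50L; n_replicates <- 100L
    n_candidates <- 100000L
    cfg <- sim_config()
  }
  structure(list(
    n_landscapes = as.integer(n_landscapes),
    n_scenarios = as.integer(n_scenarios),
    n_replicates = as.integer(n_replicates),
    n_candidates = as.integer(n_candidates), cfg = cfg,
    properties = properties, delta_e_arms = delta_e_arms, l_e = l_e,
    resolution = as.integer(resolution), l_hl_range = l_hl_range, p_l = p_l,
    share_burn_in = isTRUE(share_burn_in),
    master_seed = as.integer(master_seed), profile = profile
  ), class = "study_design")
}

# stable short hash of a configuration object, for provenance
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  sprintf("%08x", derive_seed(7L, utf8ToInt(txt)))
}

design_landscape <- function(design, ls) {
  generate_landscape(landscape_params(
    mu_e = 0, sigma_e = 1, l_e = design$l_e, resolution = design$resolution,
    seed = derive_seed(design$master_seed, 1L, ls)))
}

design_pool <- function(design, landscape, ls) {
  scenario_candidates(landscape, design$n_candidates,
                      seed = derive_seed(design$master_seed, 2L, ls),
                      l_hl_range = design$l_hl_range, p_l = design$p_l)
}

design_burn_ins <- function(design, landscape, ls) {
  lapply(seq_len(design$n_replicates), function(r)
    run_burn_in(landscape, design$cfg,
                seed = derive_seed(design$master_seed, 4L, ls, r))$state)
}

# simulate one scenario set (all scenarios x replicates x arms) and score it
simulate_set <- function(design, landscape, ls, set, prop_idx, burns) {
  cfg <- design$cfg
  recs <- list()
  for (s in seq_len(nrow(set$properties))) {
    sc <- set$scenarios[[s]]
    props <- set$properties[s, ]
    for (r in seq_len(design$n_replicates)) {
      burned <- if (design$share_burn_in) burns[[r]] else
        run_burn_in(landscape, cfg,
                    seed = derive_seed(design$master_seed, 4L, ls, r,
                                       prop_idx, s))$state
      for (a in seq_along(design$delta_e_arms)) {
        tr <- run_scenario(burned, landscape, sc, cfg,
                           delta_e = design$delta_e_arms[a],
                           seed = derive_seed(design$master_seed, 5L, ls,
                                              prop_idx, s, r, a))
        recs[[length(recs) + 1]] <- score_trajectory(
          tr, props, landscape_id = ls, scenario_id = s, replicate = r)
      }
    }
  }
  do.call(rbind, recs)
}

#' Run the main-effects design
#'
#' For every landscape: generate the landscape, draw a candidate pool,
#' select one scenario set per landscape property by weighted density
#' sampling (the focal property flattened, the others held near their
#' mean), burn populations in, and simulate every scenario for every
#' replicate under each warming arm. Outcomes are aggregated to
#' persistence proportions and, when `fit = TRUE`, the random-slope
#' persistence model is fitted per property on the environmental-change
#' arm.
#'
#' @param design A [study_design()].
#' @param fit Fit the hierarchical model per property (default `TRUE`).
#' @param fit_args Named list of extra arguments for
#'   [fit_hierarchical_logit()] (sampler settings; designs with few
#'   landscapes need longer chains).
#' @param verbose Print per-landscape progress to stderr.
#' @return List with `records` (one row per replicate run), `aggregated`
#'   (per landscape x property x scenario x arm), `fits` (named list of
#'   `posterior_summary`, one per property), `manifest` (provenance).
#' @export
run_main_design <- function(design, fit = TRUE, fit_args = list(),
                            verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  all_recs <- list()
  for (ls in seq_len(design$n_landscapes)) {
    if (verbose) message(sprintf("landscape %d/%d", ls, design$n_landscapes))
    landscape <- design_landscape(design, ls)
    pool <- design_pool(design, landscape, ls)
    burns <- if (design$share_burn_in) design_burn_ins(design, landscape, ls)
             else NULL
    for (ip in seq_along(design$properties)) {
      prop <- design$properties[ip]
      set <- sample_scenarios(landscape, n_select = design$n_scenarios,
                              focal = prop, pool = pool,
                              seed = derive_seed(design$master_seed, 3L, ls))
      recs <- simulate_set(design, landscape, ls, set, ip, burns)
      recs$property <- prop
      all_recs[[length(all_recs) + 1]] <- recs
    }
  }
  records <- do.call(rbind, all_recs)
  aggregated <- aggregate_persistence(
    records, by = c("landscape_id", "property", "scenario_id", "delta_e"))
  fits <- NULL
  if (fit) {
    change_arm <- max(design$delta_e_arms)
    fits <- lapply(stats::setNames(design$properties, design$properties),
                   function(prop) {
      d <- aggregated[aggregated$property == prop &
                        aggregated$delta_e == change_arm, ]
      do.call(fit_hierarchical_logit, c(
        list(d, prop,
             seed = derive_seed(design$master_seed, 6L,
                                match(prop, design$properties))),
        fit_args))
    })
  }
  list(records = records, aggregated = aggregated, fits = fits,
       manifest = list(master_seed = design$master_seed,
                       config_hash = config_hash(design),
                       timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
}

#' Run the pairwise two-way interaction design
#'
#' For every ordered property pair `(V1, V2)` (6 pairs) and each `V2` band
#' (~P25 and ~P75; 12 scenario sets per landscape in total), plus the
#' control set where only `V1` varies, simulates the design and fits the
#' fixed-effect interaction model on the pooled band data and per-condition
#' fixed-effect models for the slope comparison, sharing one `V1`
#' standardization across conditions.
#'
#' @param design A [study_design()] (typically with fewer scenarios).
#' @param pairs Optional list of `c(V1, V2)` pairs; default all 6 ordered
#'   pairs of the design's properties.
#' @param fit Fit models (default `TRUE`).
#' @param verbose Progress messages.
#' @return List with `records`, `aggregated`, and per-pair `fits`
#'   (`interaction` fit, per-condition fits and the `comparison` table).
#' @export
run_interaction_design <- function(design, pairs = NULL, fit = TRUE,
                                   verbose = FALSE) {
  stopifnot(inherits(design, "study_design"))
  props <- design$properties
  if (is.null(pairs)) {
    pairs <- list()
    for (a in props) for (b in props) if (a != b)
      pairs[[length(pairs) + 1]] <- c(a, b)
  }
  all_recs <- list()
  for (ls in seq_len(design$n_landscapes)) {
    if (verbose) message(sprintf("landscape %d/%d", ls, design$n_landscapes))
    landscape <- design_landscape(design, ls)
    pool <- design_pool(design, landscape, ls)
    burns <- if (design$share_burn_in) design_burn_ins(design, landscape, ls)
             else NULL
    for (ipair in seq_along(pairs)) {
      V1 <- pairs[[ipair]][1]; V2 <- pairs[[ipair]][2]
      ides <- interaction_design(pool, V1, V2, n_select = design$n_scenarios,
                                 seed = derive_seed(design$master_seed, 3L, ls,
                                                    ipair))
      ctrl <- sample_scenarios(landscape, n_select = design$n_scenarios,
                               focal = V1, pool = pool,
                               seed = derive_seed(design$master_seed, 3L, ls))
      for (cond in c("control", "low", "high")) {
        set <- switch(cond, control = ctrl, low = ides$low, high = ides$high)
        recs <- simulate_set(design, landscape, ls, set,
                             100L * ipair + match(cond, c("control", "low", "high")),
                             burns)
        recs$pair <- paste(V1, V2, sep = ":")
        recs$condition <- cond
        all_recs[[length(all_recs) + 1]] <- recs
      }
    }
  }
  records <- do.call(rbind, all_recs)
  aggregated <- aggregate_persistence(
    records, by = c("landscape_id", "pair", "condition", "scenario_id",
                    "delta_e"))
  fits <- NULL
  if (fit) {
    change_arm <- max(design$delta_e_arms)
    fits <- lapply(stats::setNames(seq_along(pairs),
                                   vapply(pairs, paste, "", collapse = ":")),
                   function(ipair) {
      V1 <- pairs[[ipair]][1]; V2 <- pairs[[ipair]][2]
      key <- paste(V1, V2, sep = ":")
      d <- aggregated[aggregated$pair == key & aggregated$delta_e == change_arm, ]
      band <- d[d$condition != "control", ]
      inter <- fit_interaction_model(
        band, V1, V2, seed = derive_seed(design$master_seed, 8L, ipair))
      # per-condition V1-slope fits on a shared V1 standardization
      tr1 <- list(center = mean(band[[V1]]), scale = stats::sd(band[[V1]]))
      cond_fit <- function(cond) fit_interaction_model(
        d[d$condition == cond, ], V1, V2,
        seed = derive_seed(design$master_seed, 9L, ipair,
                           match(cond, c("control", "low", "high"))),
        transform = tr1)
      fits_c <- lapply(stats::setNames(c("control", "low", "high"),
                                       c("control", "low", "high")), cond_fit)
      list(interaction = inter,
           conditions = fits_c,
           comparison = slope_comparison(fits_c$control, fits_c$low,
                                         fits_c$high))
    })
  }
  list(records = records, aggregated = aggregated, fits = fits,
       manifest = list(master_seed = design$master_seed,
                       config_hash = config_hash(design),
                       timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
}

#' Sensitivity analysis over model parameters
#'
#' Local mode: vary one [sim_config()] parameter at a time over a supplied
#' grid, running a reduced main design per setting. Global mode: draw
#' `n_draws` parameter combinations uniformly from supplied bounds. Each
#' setting's persistence is fitted with the random-slope model per
#' property, and the posterior slope signs are tabulated into a
#' sign-stability report.
#'
#' @param design A reduced [study_design()].
#' @param mode `"local"` or `"global"`.
#' @param grid Local mode: named list, each element a vector of values for
#'   one `sim_config` parameter.
#' @param bounds Global mode: named list of `c(lower, upper)` bounds.
#' @param n_draws Global mode: number of random parameter combinations.
#' @param fit Fit models per setting (default `TRUE`).
#' @param verbose Progress messages.
#' @return List with `settings` (parameter table), `results` (per-setting
#'   design outputs) and `stability` (parameter, value, property,
#'   posterior mean slope and sign).
#' @export
run_sensitivity <- function(design, mode = c("local", "global"), grid = NULL,
                            bounds = NULL, n_draws = 10L, fit = TRUE,
                            verbose = FALSE) {
  mode <- match.arg(mode)
  settings <- list()
  if (mode == "local") {
    stopifnot(is.list(grid), length(grid) >= 1)
    for (par in names(grid)) for (v in grid[[par]])
      settings[[length(settings) + 1]] <- stats::setNames(list(v), par)
  } else {
    stopifnot(is.list(bounds), length(bounds) >= 1)
    set.seed(derive_seed(design$master_seed, 10L))
    for (k in seq_len(n_draws)) {
      draw <- lapply(bounds, function(b) stats::runif(1, b[1], b[2]))
      settings[[length(settings) + 1]] <- draw
    }
  }
  results <- vector("list", length(settings))
  stab <- list()
  for (k in seq_along(settings)) {
    ov <- settings[[k]]
    if (verbose) message(sprintf("setting %d/%d: %s", k, length(settings),
                                 paste(names(ov), unlist(ov), sep = "=",
                                       collapse = ", ")))
    cfg_args <- utils::modifyList(
      unclass(design$cfg)[setdiff(names(unclass(design$cfg)),
                                  "habitat_choice_full")], ov)
    cfg_args$habitat_choice <-
      if (design$cfg$habitat_choice_full) "fitness" else "match"
    d2 <- design
    d2$cfg <- do.call(sim_config, cfg_args)
    d2$master_seed <- derive_seed(design$master_seed, 11L, k)
    res <- run_main_design(d2, fit = fit)
    results[[k]] <- res
    if (fit) {
      for (prop in design$properties) {
        b1 <- res$fits[[prop]]$summary
        b1 <- b1[b1$term == "b1", ]
        stab[[length(stab) + 1]] <- data.frame(
          parameter = paste(names(ov), collapse = ","),
          value = paste(signif(unlist(ov), 4), collapse = ","),
          property = prop, slope_mean = b1$mean,
          sign = sign(b1$mean))
      }
    }
  }
  list(settings = settings, results = results,
       stability = if (length(stab)) do.call(rbind, stab) else NULL)
}

#' Read a plain-text key=value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments are
#' ignored; values that parse as numbers become numeric.
#'
#' @param path File path.
#' @return Named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}
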