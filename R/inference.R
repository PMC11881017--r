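#' Standardize a predictor to z-scores
#'
#' Centers and scales by the sample SD (`n - 1` denominator), storing the
#' transform as attributes so fitted slopes can be mapped back to the
#' original scale. Landscape properties are standardized before model
#' fitting so their slopes are comparable across properties.
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Numeric z-scores with attributes `center` and `scale`.
#' @export
standardize <- function(values) {
  if (length(unique(values)) < 2)
    stop("degenerate predictor: fewer than 2 distinct values", call. = FALSE)
  ctr <- mean(values)
  scl <- stats::sd(values)
  structure((values - ctr) / scl, center = ctr, scale = scl)
}

# standardize with a data-derived or externally fixed transform
apply_transform <- function(values, transform = NULL) {
  if (is.null(transform)) return(standardize(values))
  structure((values - transform$center) / transform$scale,
            center = transform$center, scale = transform$scale)
}

# hierarchically centered parameterization (a0[j] = b0 + u0[j]), which mixes
# far better than the centered-on-zero offsets when landscapes are data-rich;
# u0/u1 are recovered as deterministic contrasts
jags_hierarchical_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], trials[i])
    logit(p[i]) <- a0[land[i]] + a1[land[i]] * V[i]
  }
  for (j in 1:J) {
    a0[j] ~ dnorm(b0, tau0)
    a1[j] ~ dnorm(b1, tau1)
    u0[j] <- a0[j] - b0
    u1[j] <- a1[j] - b1
  }
  b0 ~ dnorm(0, 0.04)
  b1 ~ dnorm(0, 0.04)
  sd0 ~ dnorm(0, 0.25) T(0,)
  sd1 ~ dnorm(0, 0.25) T(0,)
  tau0 <- pow(sd0, -2)
  tau1 <- pow(sd1, -2)
}"

jags_interaction_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dbin(p[i], trials[i])
    logit(p[i]) <- b0 + b1 * V1[i] + b2 * V2[i] + b3 * V1[i] * V2[i]
  }
  b0 ~ dnorm(0, 0.04)
  b1 ~ dnorm(0, 0.04)
  b2 ~ dnorm(0, 0.04)
  b3 ~ dnorm(0, 0.04)
}"

run_jags <- function(model_string, data, monitors, seed, n_chains, n_adapt,
                     n_burn, n_iter, thin) {
  # the glm module provides block samplers that mix far better on
  # binomial-logit hierarchies than the default slice samplers
  suppressWarnings(try(rjags::load.module("glm", quiet = TRUE), silent = TRUE))
  inits <- lapply(seq_len(n_chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, 101L, ch)))
  con <- textConnection(model_string)
  on.exit(close(con))
  jm <- rjags::jags.model(con, data = data, inits = inits,
                          n.chains = n_chains, n.adapt = n_adapt,
                          quiet = TRUE)
  stats::update(jm, n_burn, progress.bar = "none")
  rjags::coda.samples(jm, monitors, n.iter = n_iter, thin = thin,
                      progress.bar = "none")
}

summarize_draws <- function(samples) {
  m <- as.matrix(samples)
  qs <- t(apply(m, 2, stats::quantile, probs = c(0.025, 0.975)))
  data.frame(term = colnames(m), mean = colMeans(m),
             sd = apply(m, 2, stats::sd),
             q2.5 = qs[, 1], q97.5 = qs[, 2], row.names = NULL)
}

check_diagnostics <- function(samples, scalar_pars, check) {
  sub <- samples[, scalar_pars, drop = FALSE]
  rhat <- tryCatch(
    max(coda::gelman.diag(sub, autoburnin = FALSE,
                          multivariate = FALSE)$psrf[, 1]),
    error = function(e) NA_real_)
  ess <- min(coda::effectiveSize(sub))
  diag <- list(max_rhat = rhat, min_ess = ess, divergences = 0L,
               ok = isTRUE(rhat < 1.01) && ess > 400)
  if (check && !diag$ok)
    stop(sprintf(
      "sampler diagnostics failed: max Rhat = %.4f (need < 1.01), min ESS = %.0f (need > 400)",
      rhat, ess), call. = FALSE)
  diag
}

#' Fit the random-slope, random-intercept persistence model
#'
#' Bayesian logistic regression of persistence on one standardized
#' landscape property, with landscape-level random intercepts and random
#' slopes: `logit(p_persist) = (b0 + u0[landscape]) + (b1 + u1[landscape]) * V`,
#' `u0 ~ N(0, sd0)`, `u1 ~ N(0, sd1)`. Replicates are aggregated to a
#' binomial likelihood per scenario (identical to per-trial Bernoulli).
#' Priors: Normal(0, 5) on fixed effects, half-Normal(0, 2) on the
#' between-landscape SDs. Sampled with JAGS.
#'
#' @param data data.frame with columns `landscape_id`, the raw property
#'   column named by `property`, `persisted` (successes) and `trials`.
#' @param property Name of the property column (e.g. `"l_hl"`).
#' @param seed Integer seed for the sampler chains.
#' @param n_chains,n_adapt,n_burn,n_iter,thin Sampler settings.
#' @param check If `TRUE` (default) an error is raised when convergence
#'   diagnostics fail (Rhat >= 1.01 or ESS <= 400 on the fixed effects and
#'   SDs; JAGS has no divergent transitions).
#' @param transform Optional list `(center, scale)` to standardize the
#'   property with an externally fixed transform (so that several fits
#'   share one scale, as [slope_comparison()] requires); default derives
#'   the transform from `data`.
#' @return An object of class `posterior_summary`: `summary` (term, mean,
#'   sd, central 95% interval, group), `diagnostics`, `draws` (fixed
#'   effects and SDs), `ranef` (per-landscape deviations), `transform`
#'   (standardization back-map), `property`, `model`.
#' @export
fit_hierarchical_logit <- function(data, property, seed = 1L, n_chains = 2L,
                                   n_adapt = 1000L, n_burn = 1000L,
                                   n_iter = 4000L, thin = 2L, check = TRUE,
                                   transform = NULL) {
  stopifnot(all(c("landscape_id", property, "persisted", "trials") %in%
                  names(data)))
  land_levels <- sort(unique(data$landscape_id))
  if (length(land_levels) < 3)
    stop("need at least 3 landscapes for the hierarchical model", call. = FALSE)
  V <- apply_transform(data[[property]], transform)
  jd <- list(N = nrow(data), J = length(land_levels),
             y = as.integer(data$persisted),
             trials = as.integer(data$trials),
             land = match(data$landscape_id, land_levels), V = as.numeric(V))
  scalar_pars <- c("b0", "b1", "sd0", "sd1")
  samples <- run_jags(jags_hierarchical_model, jd,
                      c(scalar_pars, "u0", "u1"), seed, n_chains, n_adapt,
                      n_burn, n_iter, thin)
  diag <- check_diagnostics(samples, scalar_pars, check)
  sm <- summarize_draws(samples)
  sm$group <- ifelse(sm$term %in% c("b0", "b1"), "fixed",
                     ifelse(sm$term %in% c("sd0", "sd1"), "sd",
                            ifelse(grepl("^u0", sm$term),
                                   "landscape_intercept", "landscape_slope")))
  structure(list(
    summary = sm, diagnostics = diag,
    draws = as.matrix(samples)[, scalar_pars, drop = FALSE],
    transform = list(center = attr(V, "center"), scale = attr(V, "scale")),
    property = property, landscapes = land_levels, model = "hierarchical"
  ), class = "posterior_summary")
}

#' Fit the fixed-effect two-way interaction persistence model
#'
#' `logit(p_persist) = b0 + b1 V1 + b2 V2 + b3 V1 V2` on standardized
#' properties, with Normal(0, 5) priors; binomial likelihood as in
#' [fit_hierarchical_logit()].
#'
#' @param data data.frame with the two raw property columns, `persisted`
#'   and `trials`.
#' @param V1,V2 Names of the two (distinct) property columns.
#' @param transform2 Optional fixed `(center, scale)` transform for `V2`.
#' @inheritParams fit_hierarchical_logit
#' @return A `posterior_summary` (model `"interaction"`).
#' @export
fit_interaction_model <- function(data, V1, V2, seed = 1L, n_chains = 2L,
                                  n_adapt = 1000L, n_burn = 1000L,
                                  n_iter = 4000L, thin = 2L, check = TRUE,
                                  transform = NULL, transform2 = NULL) {
  if (identical(V1, V2)) stop("`V1` and `V2` must differ", call. = FALSE)
  stopifnot(all(c(V1, V2, "persisted", "trials") %in% names(data)))
  z1 <- apply_transform(data[[V1]], transform)
  z2 <- apply_transform(data[[V2]], transform2)
  jd <- list(N = nrow(data), y = as.integer(data$persisted),
             trials = as.integer(data$trials),
             V1 = as.numeric(z1), V2 = as.numeric(z2))
  scalar_pars <- c("b0", "b1", "b2", "b3")
  samples <- run_jags(jags_interaction_model, jd, scalar_pars, seed,
                      n_chains, n_adapt, n_burn, n_iter, thin)
  diag <- check_diagnostics(samples, scalar_pars, check)
  sm <- summarize_draws(samples)
  sm$group <- "fixed"
  structure(list(
    summary = sm, diagnostics = diag,
    draws = as.matrix(samples)[, scalar_pars, drop = FALSE],
    transform = list(
      V1 = list(center = attr(z1, "center"), scale = attr(z1, "scale")),
      V2 = list(center = attr(z2, "center"), scale = attr(z2, "scale"))),
    property = c(V1, V2), model = "interaction"
  ), class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("<posterior_summary> %s model (%s)\n", x$model,
              paste(x$property, collapse = " x ")))
  print(x$summary[x$summary$group %in% c("fixed", "sd"), ], row.names = FALSE)
  cat(sprintf("diagnostics: max Rhat %.4f, min ESS %.0f\n",
              x$diagnostics$max_rhat, x$diagnostics$min_ess))
  invisible(x)
}

slope_row <- function(fit, term, condition) {
  r <- fit$summary[fit$summary$term == term, ]
  data.frame(condition = condition, term = term, mean = r$mean, sd = r$sd,
             q2.5 = r$q2.5, q97.5 = r$q97.5)
}

#' Compare focal-property slopes across interaction bands
#'
#' Tabulates the posterior slope of the focal (fully varying) property for
#' the control fit and the fits with the second property held at its low
#' (~P25) and high (~P75) bands, and flags slope pairs whose central 95%
#' intervals do not overlap. All three fits must share the same
#' standardization transform for the focal property.
#'
#' @param control,low,high `posterior_summary` objects on a common focal
#'   property scale (`control` from the main design, `low`/`high` from the
#'   interaction bands).
#' @param tol Relative tolerance for the shared-transform check.
#' @return data.frame with one row per condition plus logical columns
#'   `flag_low_vs_control`, `flag_high_vs_control`, `flag_low_vs_high`
#'   repeated on each row's attributes.
#' @export
slope_comparison <- function(control, low, high, tol = 1e-6) {
  if (is.null(control) || is.null(low) || is.null(high))
    stop("all three fits (control, low, high) are required", call. = FALSE)
  tr <- function(f) if (f$model == "hierarchical") f$transform else f$transform$V1
  t0 <- tr(control)
  for (f in list(low, high)) {
    t1 <- tr(f)
    if (abs(t1$center - t0$center) > tol * max(1, abs(t0$center)) ||
        abs(t1$scale - t0$scale) > tol * t0$scale)
      stop("mismatched standardization transforms between fits", call. = FALSE)
  }
  term <- "b1"
  tab <- rbind(slope_row(control, term, "control"),
               slope_row(low, term, "V2_low"),
               slope_row(high, term, "V2_high"))
  overlap <- function(a, b) !(a$q97.5 < b$q2.5 || b$q97.5 < a$q2.5)
  tab$nonoverlap_vs_control <- c(
    FALSE,
    !overlap(tab[2, ], tab[1, ]),
    !overlap(tab[3, ], tab[1, ]))
  attr(tab, "low_high_nonoverlap") <- !overlap(tab[2, ], tab[3, ])
  tab
}

#' Write a posterior summary as TSV
#'
#' @param fit A `posterior_summary`.
#' @param path Output path.
#' @export
write_posterior <- function(fit, path) {
  utils::write.table(fit$summary, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
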