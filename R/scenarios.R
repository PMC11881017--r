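#' Generate a binary habitat-loss map
#'
#' A habitat-loss map is produced exactly like an environmental landscape —
#' a periodic Gaussian random field with autocorrelation length `l_hl` —
#' except that the continuous field is converted to binary by a quantile
#' threshold: the `p_l` highest-valued fraction of cells (those above the
#' field's empirical `1 - p_l` quantile) is destroyed. Larger `l_hl`
#' produces spatially clumpier loss and hence larger contiguous remnant
#' patches; the destroyed fraction equals `p_l` up to quantile ties
#' (at most one cell in `resolution^2`).
#'
#' @param l_hl Autocorrelation length of the loss field (fraction of the
#'   landscape side, positive).
#' @param p_l Proportion of the landscape destroyed, in `[0, 1)`.
#' @param resolution Grid cells per side; must match the landscape the map
#'   will be applied to.
#' @param seed Integer RNG seed.
#' @return An object of class `loss_scenario`: list with `loss_grid`
#'   (integer matrix, 1 = destroyed, 0 = habitat), `l_hl`, `p_l`, `seed`.
#' @export
generate_loss_map <- function(l_hl, p_l, resolution = 128L, seed = 1L) {
  if (!is.finite(p_l) || p_l < 0 || p_l >= 1)
    stop("`p_l` must be in [0, 1)", call. = FALSE)
  if (!is.finite(l_hl) || l_hl <= 0)
    stop("`l_hl` must be positive", call. = FALSE)
  resolution <- as.integer(resolution)
  set.seed(seed)
  f <- periodic_grf(resolution, l_hl)
  lg <- matrix(0L, resolution, resolution)
  if (p_l > 0) {
    thr <- quantile7(f, 1 - p_l)
    lg[f > thr] <- 1L
  }
  structure(list(loss_grid = lg, l_hl = l_hl, p_l = p_l,
                 seed = as.integer(seed)),
            class = "loss_scenario")
}

#' @export
print.loss_scenario <- function(x, ...) {
  cat(sprintf("<loss_scenario> %dx%d | l_hl=%.3g p_l=%.3g seed=%d | lost=%.4f\n",
              nrow(x$loss_grid), ncol(x$loss_grid), x$l_hl, x$p_l, x$seed,
              mean(x$loss_grid)))
  invisible(x)
}

#' Trimmed environmental breadth and its change under habitat loss
#'
#' The environmental breadth of a set of cells is the range of its values
#' after discarding values at or beyond that set's own 2.5th and 97.5th
#' percentiles (strict inequalities), which damps low-frequency outliers.
#' `B1` is the breadth of the intact landscape, `B2` the breadth of the
#' remaining habitat, and the breadth loss is `delta_Be = B2 - B1`
#' (non-positive in expectation; negative when loss narrows the range of
#' available conditions).
#'
#' @param landscape An `env_landscape`.
#' @param scenario A `loss_scenario` on the same grid.
#' @return List with `B1`, `B2`, `delta_Be`.
#' @export
breadth_loss <- function(landscape, scenario) {
  stopifnot(all(dim(landscape$grid) == dim(scenario$loss_grid)))
  B1 <- trimmed_breadth(as.vector(landscape$grid))
  remaining <- landscape$grid[scenario$loss_grid == 0L]
  B2 <- trimmed_breadth(remaining)
  list(B1 = B1, B2 = B2, delta_Be = B2 - B1)
}

trimmed_breadth <- function(v) {
  if (length(v) < 2) stop("degenerate scenario: too few remaining cells",
                          call. = FALSE)
  q <- quantile7(v, c(0.025, 0.975))
  inside <- v[v > q[1] & v < q[2]]
  if (length(inside) < 2)
    stop("degenerate scenario: fewer than 2 cells inside the trim band",
         call. = FALSE)
  max(inside) - min(inside)
}

#' Shift in mean environmental condition under habitat loss
#'
#' Mean environmental value of the remaining habitat minus the mean of the
#' intact landscape; destroyed cells are treated as missing. Positive when
#' loss is concentrated on the low (cool) end of the gradient.
#'
#' @inheritParams breadth_loss
#' @return Scalar `delta_mu_e` (environment units).
#' @export
mean_shift <- function(landscape, scenario) {
  stopifnot(all(dim(landscape$grid) == dim(scenario$loss_grid)))
  remaining <- landscape$grid[scenario$loss_grid == 0L]
  if (length(remaining) == 0)
    stop("degenerate scenario: all habitat destroyed", call. = FALSE)
  mean(remaining) - mean(landscape$grid)
}

#' All landscape properties of a habitat-loss scenario
#'
#' @inheritParams breadth_loss
#' @return One-row data.frame: `l_hl`, `p_l`, `seed`, `delta_Be`,
#'   `delta_mu_e`, `B1`, `B2`, `mu_e_prime`, `fraction_lost`, `degenerate`.
#' @export
scenario_properties <- function(landscape, scenario) {
  fl <- mean(scenario$loss_grid)
  out <- data.frame(l_hl = scenario$l_hl, p_l = scenario$p_l,
                    seed = scenario$seed, delta_Be = NA_real_,
                    delta_mu_e = NA_real_, B1 = NA_real_, B2 = NA_real_,
                    mu_e_prime = NA_real_, fraction_lost = fl,
                    degenerate = FALSE)
  res <- try({
    b <- breadth_loss(landscape, scenario)
    dm <- mean_shift(landscape, scenario)
    out$delta_Be <- b$delta_Be; out$B1 <- b$B1; out$B2 <- b$B2
    out$delta_mu_e <- dm
    out$mu_e_prime <- mean(landscape$grid) + dm
  }, silent = TRUE)
  if (inherits(res, "try-error")) out$degenerate <- TRUE
  out
}

#' Connected-patch sizes of a binary map on the torus
#'
#' Sizes (cell counts) of 4-connected components, with adjacency wrapping
#' across the grid edges. Used as the fragmentation oracle: loss maps with
#' larger `l_hl` leave larger remnant habitat patches.
#'
#' @param scenario A `loss_scenario`.
#' @param of `"habitat"` (default) for remaining-habitat patches, `"lost"`
#'   for destroyed patches.
#' @return Integer vector of component sizes (decreasing).
#' @export
patch_sizes <- function(scenario, of = c("habitat", "lost")) {
  of <- match.arg(of)
  keep <- if (of == "habitat") scenario$loss_grid == 0L else scenario$loss_grid == 1L
  R <- nrow(keep)
  idx <- matrix(seq_len(R * R), R, R)
  right <- idx[, c(seq_len(R)[-1], 1)]
  down <- idx[c(seq_len(R)[-1], 1), ]
  keep_r <- keep & keep[, c(seq_len(R)[-1], 1)]
  keep_d <- keep & keep[c(seq_len(R)[-1], 1), ]
  edges <- rbind(cbind(idx[keep_r], right[keep_r]),
                 cbind(idx[keep_d], down[keep_d]))
  g <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2),
                                   directed = FALSE)
  isolated <- sum(keep) - length(unique(as.vector(edges)))
  comp <- igraph::components(g)
  sort(c(comp$csize, rep(1L, isolated)), decreasing = TRUE)
}

#' Generate a candidate pool of habitat-loss scenarios
#'
#' Draws `n` loss maps with `l_hl` uniform on `l_hl_range` and independent
#' seeds, computes the three landscape properties of each against
#' `landscape`, and returns a property table. Grids are not retained —
#' a candidate is fully determined by `(l_hl, p_l, seed)` and can be
#' re-materialized with [generate_loss_map()].
#'
#' @param landscape An `env_landscape`.
#' @param n Number of candidates.
#' @param seed Master seed for the pool.
#' @param l_hl_range Range of loss autocorrelation lengths sampled.
#' @param p_l Destroyed fraction (default 2/3, the study-wide value).
#' @return data.frame of candidate properties (degenerate candidates are
#'   dropped), with attribute `resolution`.
#' @export
scenario_candidates <- function(landscape, n, seed = 1L,
                                l_hl_range = c(0.01, 0.25), p_l = 2 / 3) {
  R <- landscape$params$resolution
  set.seed(derive_seed(seed, 911L))
  lhl <- stats::runif(n, l_hl_range[1], l_hl_range[2])
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- generate_loss_map(lhl[i], p_l, R, seed = derive_seed(seed, 913L, i))
    rows[[i]] <- scenario_properties(landscape, sc)
  }
  out <- do.call(rbind, rows)
  out$cand_id <- seq_len(n)
  out <- out[!out$degenerate, ]
  attr(out, "resolution") <- R
  out
}

# inverse-kernel-density selection weights on a focal property (Silverman
# bandwidth); flattens the selected marginal toward uniform over the range
inv_density_weights <- function(v) {
  d <- stats::density(v, bw = "nrd0")
  1 / pmax(stats::approx(d$x, d$y, xout = v, rule = 2)$y, 1e-12)
}

#' Select habitat-loss scenarios spanning a wide range of one property
#'
#' Weighted density sampling: from a candidate pool, `n_select` scenarios
#' are drawn without replacement with probability inversely proportional to
#' the kernel density of the focal property, which flattens its marginal
#' (capturing a wide, evenly covered range of values). The two non-focal
#' properties are constrained to lie near their candidate-pool means (within
#' `band_sd` pooled SDs), so that only the focal property varies.
#'
#' @param landscape An `env_landscape`.
#' @param n_candidates Candidate-pool size (ignored if `pool` is given).
#' @param n_select Number of scenarios to select.
#' @param focal One of `"delta_Be"`, `"delta_mu_e"`, `"l_hl"`.
#' @param seed Master seed (pool generation and selection).
#' @param pool Optional precomputed [scenario_candidates()] table, shared
#'   across the three focal properties of a design.
#' @param constrain If `FALSE`, no non-focal band is imposed.
#' @param band_sd Half-width of the non-focal constraint band, in pooled SDs.
#' @param ... Passed to [scenario_candidates()].
#' @return List with `properties` (selected rows, plus `scenario_id`) and
#'   `scenarios` (the materialized `loss_scenario` objects).
#' @export
sample_scenarios <- function(landscape, n_candidates = 2000L, n_select = 50L,
                             focal = c("delta_Be", "delta_mu_e", "l_hl"),
                             seed = 1L, pool = NULL, constrain = TRUE,
                             band_sd = 0.25, ...) {
  focal <- match.arg(focal)
  if (is.null(pool))
    pool <- scenario_candidates(landscape, n_candidates, seed = seed, ...)
  if (n_select > nrow(pool))
    stop("`n_select` exceeds the number of (non-degenerate) candidates",
         call. = FALSE)
  others <- setdiff(c("delta_Be", "delta_mu_e", "l_hl"), focal)
  eligible <- rep(TRUE, nrow(pool))
  if (constrain) {
    for (v in others) {
      z <- (pool[[v]] - mean(pool[[v]])) / stats::sd(pool[[v]])
      eligible <- eligible & abs(z) <= band_sd
    }
  }
  if (sum(eligible) < n_select)
    stop(sprintf(
      "infeasible constraint: %d candidates in the non-focal band, %d needed",
      sum(eligible), n_select), call. = FALSE)
  sub <- pool[eligible, ]
  set.seed(derive_seed(seed, 917L, match(focal, c("delta_Be", "delta_mu_e", "l_hl"))))
  if (n_select == nrow(sub)) {
    pick <- seq_len(nrow(sub))
  } else {
    pick <- sample.int(nrow(sub), n_select,
                       prob = inv_density_weights(sub[[focal]]))
  }
  sel <- sub[pick, ]
  sel$scenario_id <- seq_len(nrow(sel))
  R <- attr(pool, "resolution")
  scen <- lapply(seq_len(nrow(sel)), function(i)
    generate_loss_map(sel$l_hl[i], sel$p_l[i], R, seed = sel$seed[i]))
  list(properties = sel, scenarios = scen, focal = focal)
}

#' Scenario sets for a pairwise interaction design
#'
#' For an ordered property pair `(V1, V2)`: `V1` is allowed to vary fully
#' (its marginal flattened by inverse-density weighting), `V2` is held in a
#' narrow band (half-width `0.1` pooled SDs) around either the ~25th or the
#' ~75th percentile of its candidate distribution, and the third property is
#' held near its mean (within `0.25` pooled SDs). Returns both bands.
#'
#' @param pool A [scenario_candidates()] table.
#' @param V1,V2 Distinct property names from `delta_Be`, `delta_mu_e`,
#'   `l_hl`.
#' @param n_select Scenarios per set.
#' @param seed Selection seed.
#' @return List with elements `low` and `high`, each as the return value of
#'   [sample_scenarios()] restricted to the band.
#' @export
interaction_design <- function(pool, V1, V2, n_select = 50L, seed = 1L) {
  props <- c("delta_Be", "delta_mu_e", "l_hl")
  V1 <- match.arg(V1, props); V2 <- match.arg(V2, props)
  if (V1 == V2) stop("`V1` and `V2` must differ", call. = FALSE)
  V3 <- setdiff(props, c(V1, V2))
  sd2 <- stats::sd(pool[[V2]])
  z3 <- (pool[[V3]] - mean(pool[[V3]])) / stats::sd(pool[[V3]])
  R <- attr(pool, "resolution")
  one_band <- function(q, tag) {
    center <- quantile7(pool[[V2]], q)
    eligible <- abs(pool[[V2]] - center) <= 0.1 * sd2 & abs(z3) <= 0.25
    if (sum(eligible) < n_select)
      stop(sprintf(
        "infeasible constraint: %d candidates in the V2 %s band, %d needed",
        sum(eligible), tag, n_select), call. = FALSE)
    sub <- pool[eligible, ]
    set.seed(derive_seed(seed, 919L, match(V1, props), match(V2, props),
                         round(q * 100)))
    pick <- if (n_select == nrow(sub)) seq_len(nrow(sub))
            else sample.int(nrow(sub), n_select,
                            prob = inv_density_weights(sub[[V1]]))
    sel <- sub[pick, ]
    sel$scenario_id <- seq_len(nrow(sel))
    scen <- lapply(seq_len(nrow(sel)), function(i)
      generate_loss_map(sel$l_hl[i], sel$p_l[i], R, seed = sel$seed[i]))
    list(properties = sel, scenarios = scen, focal = V1)
  }
  list(low = one_band(0.25, "P25"), high = one_band(0.75, "P75"),
       V1 = V1, V2 = V2)
}

#' Write a scenario property table as TSV
#'
#' @param properties A properties data.frame (from [sample_scenarios()] or
#'   [scenario_candidates()]), optionally with `landscape_id` column.
#' @param path Output path.
#' @export
write_scenarios <- function(properties, path) {
  utils::write.table(properties, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
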