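test_that("loss maps destroy the requested fraction via quantile thresholding", {
  # empty-loss identity
  s0 <- generate_loss_map(0.1, 0, 64, seed = 1)
  expect_equal(sum(s0$loss_grid), 0)
  # the study-wide loss amount: 2/3 of the landscape, to within one cell
  for (seed in 1:3) {
    s <- generate_loss_map(0.08, 2 / 3, 128, seed = seed)
    expect_lte(abs(mean(s$loss_grid) - 2 / 3), 1 / 128^2)
  }
  # fraction contract holds across p_l values and resolutions
  for (p_l in c(0.25, 0.5, 8 / 15)) {
    s <- generate_loss_map(0.05, p_l, 64, seed = 4)
    expect_lte(abs(mean(s$loss_grid) - p_l), 1 / 64^2)
  }
  expect_error(generate_loss_map(0.1, 1), "p_l")
  expect_error(generate_loss_map(0.1, -0.1), "p_l")
  expect_error(generate_loss_map(0, 0.5), "l_hl")
})

test_that("larger loss autocorrelation length produces larger connected habitat patches", {
  mean_patch <- function(l_hl) mean(vapply(1:20, function(s) {
    sc <- generate_loss_map(l_hl, 2 / 3, 64, seed = s)
    mean(patch_sizes(sc, "habitat"))
  }, numeric(1)))
  expect_gt(mean_patch(0.15), mean_patch(0.02))
})

test_that("patch labelling respects torus adjacency", {
  # a band touching both vertical edges is one patch on the torus
  m <- matrix(1L, 8, 8)
  m[, c(1, 2, 7, 8)] <- 0L  # habitat columns wrap across the seam
  sc <- fx_scenario_from_matrix(m)
  expect_equal(patch_sizes(sc, "habitat"), 32L)
})

test_that("trimmed breadth loss matches an explicit order-statistic oracle on a printed toy grid", {
  vals <- (0:99) / 100
  g <- matrix(vals, 10, 10)
  L <- fx_landscape_from_matrix(g)
  sc <- fx_scenario_from_matrix(matrix(as.integer(g >= 0.5), 10, 10))
  # oracle: type-7 quantiles and strict inequalities, written out directly
  oracle_breadth <- function(v) {
    q <- unname(quantile(v, c(0.025, 0.975), type = 7))
    inside <- v[v > q[1] & v < q[2]]
    max(inside) - min(inside)
  }
  B1_exp <- oracle_breadth(vals)
  B2_exp <- oracle_breadth(vals[vals < 0.5])
  b <- breadth_loss(L, sc)
  expect_equal(b$B1, B1_exp)
  expect_equal(b$B2, B2_exp)
  expect_equal(b$delta_Be, B2_exp - B1_exp)
  expect_lt(b$delta_Be, 0)
  # no-loss scenario: breadths identical
  b0 <- breadth_loss(L, fx_scenario_from_matrix(matrix(0L, 10, 10)))
  expect_equal(b0$delta_Be, 0)
})

test_that("mean shift is the remaining-habitat mean minus the landscape mean", {
  g <- matrix(c(1, 2, 3, 4), 2, 2)
  L <- fx_landscape_from_matrix(g)
  destroy_12 <- fx_scenario_from_matrix(matrix(c(1, 1, 0, 0), 2, 2))
  destroy_34 <- fx_scenario_from_matrix(matrix(c(0, 0, 1, 1), 2, 2))
  none <- fx_scenario_from_matrix(matrix(0, 2, 2))
  expect_equal(mean_shift(L, destroy_12), 3.5 - 2.5)
  expect_equal(mean_shift(L, destroy_34), -1.0)
  expect_equal(mean_shift(L, none), 0)
  all_gone <- fx_scenario_from_matrix(matrix(1, 2, 2))
  expect_error(mean_shift(L, all_gone), "degenerate")
})

test_that("spatially unbiased loss leaves breadth and mean approximately unchanged", {
  L <- fx_landscape(seed = 13)
  n <- 64 * 64
  dbe <- dmu <- numeric(20)
  set.seed(31)
  for (k in 1:20) {
    m <- matrix(0L, 64, 64)
    m[sample.int(n, round(2 / 3 * n))] <- 1L
    sc <- fx_scenario_from_matrix(m)
    dbe[k] <- breadth_loss(L, sc)$delta_Be
    dmu[k] <- mean_shift(L, sc)
  }
  B1 <- breadth_loss(L, fx_scenario_from_matrix(matrix(0L, 64, 64)))$B1
  expect_lt(abs(mean(dbe)), 0.05 * B1)
  expect_lt(abs(mean(dmu)), 2 * sd(dmu) / sqrt(20))
})

test_that("stored scenario properties are exactly reproducible from the grids", {
  L <- fx_landscape(seed = 17)
  pool <- scenario_candidates(L, 30, seed = 5)
  for (i in sample.int(nrow(pool), 5)) {
    sc <- generate_loss_map(pool$l_hl[i], pool$p_l[i], 64, seed = pool$seed[i])
    expect_identical(breadth_loss(L, sc)$delta_Be, pool$delta_Be[i])
    expect_identical(mean_shift(L, sc), pool$delta_mu_e[i])
    expect_identical(mean(sc$loss_grid), pool$fraction_lost[i])
  }
})

test_that("weighted density sampling flattens and widens the focal marginal", {
  L <- fx_landscape(seed = 3)
  pool <- scenario_candidates(L, 2000, seed = 7)
  sel <- sample_scenarios(L, n_select = 50, focal = "delta_Be", seed = 7,
                          pool = pool, constrain = FALSE)
  v <- sel$properties$delta_Be
  pool_rng <- diff(range(pool$delta_Be))
  expect_gte(diff(range(v)) / pool_rng, 0.8)
  # flatness: bin-count CV smaller than for uniform-random picks
  brks <- seq(min(pool$delta_Be), max(pool$delta_Be), length.out = 11)
  cv <- function(x) sd(x) / mean(x)
  cv_sel <- cv(tabulate(cut(v, brks, include.lowest = TRUE), 10))
  set.seed(99)
  cv_rand <- mean(replicate(40, {
    r <- pool$delta_Be[sample.int(nrow(pool), 50)]
    cv(tabulate(cut(r, brks, include.lowest = TRUE), 10))
  }))
  expect_lt(cv_sel, cv_rand)
  # determinism: identical call, identical selection
  sel2 <- sample_scenarios(L, n_select = 50, focal = "delta_Be", seed = 7,
                           pool = pool, constrain = FALSE)
  expect_identical(sel$properties, sel2$properties)
  # constrained selection holds the non-focal properties near their means
  selc <- sample_scenarios(L, n_select = 20, focal = "delta_Be", seed = 8,
                           pool = pool)
  for (v2 in c("delta_mu_e", "l_hl")) {
    z <- abs(selc$properties[[v2]] - mean(pool[[v2]])) / sd(pool[[v2]])
    expect_true(all(z <= 0.25))
  }
  # exhaustive selection: all candidates back
  small <- scenario_candidates(L, 12, seed = 9)
  all_sel <- sample_scenarios(L, n_select = nrow(small), focal = "l_hl",
                              seed = 1, pool = small, constrain = FALSE)
  expect_setequal(all_sel$properties$cand_id, small$cand_id)
  # infeasible constraints are reported with the shortfall
  expect_error(
    sample_scenarios(L, n_select = 12, focal = "l_hl", seed = 1, pool = small),
    "infeasible|exceeds")
})

test_that("interaction designs pin the second property at its low or high band", {
  L <- fx_landscape(seed = 3)
  pool <- scenario_candidates(L, 2000, seed = 7)
  expect_error(interaction_design(pool, "l_hl", "l_hl", 10), "differ")
  ides <- interaction_design(pool, "delta_Be", "l_hl", n_select = 10, seed = 2)
  med <- median(pool$l_hl)
  expect_lt(mean(ides$low$properties$l_hl), med)
  expect_gt(mean(ides$high$properties$l_hl), med)
  # all ordered pairs x 2 bands = 12 scenario sets
  props <- c("delta_Be", "delta_mu_e", "l_hl")
  sets <- 0
  for (a in props) for (b in props) if (a != b) {
    d <- interaction_design(pool, a, b, n_select = 10, seed = 3)
    sets <- sets + length(intersect(names(d), c("low", "high")))
  }
  expect_equal(sets, 12)
})
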