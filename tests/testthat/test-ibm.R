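test_that("competition kernel follows the Gaussian form with a 3-sigma cutoff", {
  sp <- 0.02
  expect_equal(competition_kernel(0, sp), 1)
  expect_equal(competition_kernel(sp, sp), exp(-1 / 2))
  expect_equal(competition_kernel(3 * sp, sp), 0)   # at the cutoff: excluded
  expect_equal(competition_kernel(10 * sp, sp), 0)
  expect_error(competition_kernel(0.1, 0), "sigma_p")
})

test_that("indexed total competition equals the naive all-pairs sum", {
  set.seed(41)
  x <- runif(500); y <- runif(500)
  for (sp in c(0.02, 0.05, 0.2, 0.6)) {  # 0.6: radius > 1, brute-force path
    expect_equal(total_competition(x, y, sp, "indexed"),
                 total_competition(x, y, sp, "naive"), tolerance = 1e-12)
  }
  # clustered near the torus seam
  xs <- c(runif(100, 0, 0.03), runif(100, 0.97, 1))
  ys <- runif(200)
  expect_equal(total_competition(xs, ys, 0.02, "indexed"),
               total_competition(xs, ys, 0.02, "naive"), tolerance = 1e-12)
  # degenerate cases
  expect_equal(total_competition(0.5, 0.5, 0.02), 0)       # single individual
  expect_equal(total_competition(c(0.2, 0.2), c(0.4, 0.4), 0.02),
               c(1, 1))                                     # coincident pair
})

test_that("sigma_b ramps linearly from sigma_b0 to 1 at the end of the burn-in", {
  expect_equal(sigma_b_schedule(10000, 10000), 1)
  expect_equal(sigma_b_schedule(20000, 10000), 1)
  expect_equal(sigma_b_schedule(5000, 10000, sigma_b0 = 0.1), 0.55)
  expect_equal(sigma_b_schedule(0, 10000, sigma_b0 = 0.1), 0.1)
  g <- seq(0, 15000, by = 250)
  expect_true(all(diff(sigma_b_schedule(g, 10000)) >= 0))
  # shortened burn-ins keep the shape
  expect_equal(sigma_b_schedule(750, 1500, 0.1), 0.55)
})

test_that("fitness is 1 at a perfect match and decreases with crowding and mismatch", {
  cfg <- sim_config()
  # perfect match at the density where the competition factor is exactly 1
  C_star <- 2 * pi * cfg$sigma_p^2 * cfg$K
  expect_equal(fitness_weight(0.7, 0.7, C_star, cfg, sigma_b = 1), 1)
  # the matching component is 1 at P = e regardless of sigma_b
  for (sb in c(0.1, 0.5, 1)) expect_equal(match_component(2, 2, sb, 0.5), 1)
  # strictly decreasing in C_i above the clamp
  Cs <- C_star * c(1, 2, 4, 8)
  ws <- fitness_weight(0, 0, Cs, cfg)
  expect_true(all(diff(ws) < 0))
  # strictly decreasing in |P - e|
  devs <- c(0, 0.25, 0.5, 1, 2)
  wd <- fitness_weight(devs, 0, C_star, cfg)
  expect_true(all(diff(wd) < 0))
  # no neighbours: factor capped at 1, not infinite
  expect_equal(fitness_weight(0, 0, 0, cfg), 1)
  # destroyed habitat sentinel
  expect_equal(fitness_weight(0, NA, C_star, cfg), 0)
  expect_error(sim_config(sigma_f = 0), "sigma_f")
})

test_that("phenotype is the per-copy sum of QTL effects over both haplotypes", {
  al <- data.frame(effect = c(0.5, -0.2), group = c(0L, 1L), site = c(10L, 20L))
  st <- fx_state(x = c(0.1, 0.2, 0.3), y = c(0.1, 0.2, 0.3),
                 hapA = list(integer(0), 0L, 0L),
                 hapB = list(integer(0), 1L, 0L), alleles = al)
  expect_equal(phenotype_of(st, 1), 0)            # empty genome
  expect_equal(phenotype_of(st, 2), 0.3)          # heterozygous {+0.5, -0.2}
  expect_equal(phenotype_of(st, 3), 1.0)          # homozygous +0.5 counts twice
  expect_equal(st$phen, phenotype_of(st))
})

test_that("mate selection takes the strictly nearest neighbour within range, ties to the lowest id", {
  sp <- 0.02
  # two candidates at sigma_p and 2 sigma_p: nearer one wins
  st <- fx_state(x = c(0.5, 0.52, 0.54), y = rep(0.5, 3),
                 hapA = rep(list(integer(0)), 3), hapB = rep(list(integer(0)), 3))
  expect_equal(select_mate(st, 1, sp), 2L)
  # out of range: no mate, no reproduction
  far <- fx_state(x = c(0.1, 0.5), y = c(0.1, 0.5),
                  hapA = rep(list(integer(0)), 2), hapB = rep(list(integer(0)), 2))
  expect_true(is.na(select_mate(far, 1, sp)))
  # exact tie at equal distance: deterministic lowest id
  tie <- fx_state(x = c(0.5, 0.52, 0.48), y = rep(0.5, 3),
                  hapA = rep(list(integer(0)), 3), hapB = rep(list(integer(0)), 3))
  expect_equal(select_mate(tie, 1, sp), 2L)
  # distances wrap around the torus
  wrap <- fx_state(x = c(0.01, 0.98, 0.06), y = rep(0.5, 3),
                   hapA = rep(list(integer(0)), 3), hapB = rep(list(integer(0)), 3))
  expect_equal(select_mate(wrap, 1, sp), 2L)
})

test_that("offspring numbers are Poisson(lambda_0) and positions equal parent 1's position", {
  L <- fx_landscape()
  # survival forced to ~1 (huge K, flat matching) so births are observed
  # directly and nobody moves (candidate fitness never strictly higher)
  cfg <- sim_config(K = 1e8, sigma_f = 1e6, lambda_0 = 0.4, burn_in = 10L)
  npairs <- 300
  set.seed(55)
  px <- runif(npairs); py <- runif(npairs)
  st <- fx_state(x = rep(px, each = 2), y = rep(py, each = 2),
                 hapA = rep(list(integer(0)), 2 * npairs),
                 hapB = rep(list(integer(0)), 2 * npairs))
  res <- step_generation(st, L, cfg, n_gen = 1, seed = 77)
  births <- length(res$state$x) - 2 * npairs
  lam_mean <- 2 * npairs * 0.4
  lam_se <- sqrt(2 * npairs * 0.4)
  expect_gt(births, lam_mean - 3 * lam_se)
  expect_lt(births, lam_mean + 3 * lam_se)
  # every newborn sits exactly on a parental location
  newborn <- res$state$age == 0
  expect_true(all(res$state$x[newborn] %in% px))
  expect_true(all(res$state$y[newborn] %in% py))
  # degenerate Poisson: lambda_0 = 0 never produces offspring
  cfg0 <- sim_config(K = 1e8, sigma_f = 1e6, lambda_0 = 0, burn_in = 10L)
  res0 <- step_generation(st, L, cfg0, n_gen = 1, seed = 78)
  expect_equal(length(res0$state$x), 2 * npairs)
})

test_that("mutations are frozen after the burn-in: the allele registry stops growing", {
  L <- fx_landscape()
  cfg <- fx_cfg(burn_in = 30L)
  bi <- run_burn_in(L, cfg, seed = 19)
  st <- bi$state
  expect_gt(length(st$allele_effect), 0)  # mutation was active during burn-in
  reg_size <- length(st$allele_effect)
  res <- step_generation(st, L, cfg, n_gen = 50, seed = 20)
  expect_equal(length(res$state$allele_effect), reg_size)
  # segregating alleles can only be lost
  expect_true(all(diff(res$census$n_alleles) <= 0))
  expect_lte(max(res$census$n_alleles), n_segregating(st))
})

test_that("trajectories are deterministic under a fixed seed and extinction is absorbing", {
  L <- fx_landscape()
  cfg <- fx_cfg()
  bi <- fx_burnin()
  r1 <- step_generation(bi$state, L, cfg, n_gen = 30, seed = 5)
  r2 <- step_generation(bi$state, L, cfg, n_gen = 30, seed = 5)
  expect_identical(r1$census, r2$census)
  expect_identical(r1$state$x, r2$state$x)
  # empty population is a fixed point
  empty <- fx_state(numeric(0), numeric(0), list(), list())
  re <- step_generation(empty, L, cfg, n_gen = 5, seed = 6)
  expect_equal(re$census$n_alive, rep(0, 5))
})

test_that("no individual outlives the 10-generation age cap", {
  bi <- fx_burnin()
  res <- step_generation(bi$state, fx_landscape(), fx_cfg(), n_gen = 100,
                         seed = 8)
  expect_true(all(res$census$max_age <= 10))
})

test_that("cached phenotypes equal genome recomputation after long runs", {
  st <- fx_burnin()$state
  expect_equal(st$phen, phenotype_of(st), tolerance = 1e-12)
})

test_that("burn-in produces a locally adapted, density-regulated population", {
  bi <- fx_burnin()
  st <- bi$state
  K <- fx_cfg()$K
  expect_gte(length(st$x), 0.5 * K)
  expect_lte(length(st$x), 1.5 * K)
  e <- env_at(fx_landscape(), st$x, st$y)
  expect_gt(cor(st$phen, e), 0.3)
  # initialization starts from empty genomes
  st0 <- new_population(fx_cfg(), seed = 1)
  expect_equal(n_segregating(st0), 0)
  expect_true(all(st0$phen == 0))
})

test_that("habitat loss removes exactly the individuals on destroyed cells, in one step", {
  bi <- fx_burnin()
  st <- bi$state
  # no-loss scenario: unchanged
  none <- fx_scenario_from_matrix(matrix(0L, 64, 64))
  expect_identical(apply_habitat_loss(st, none)$id, st$id)
  # full loss: immediate extinction
  all_loss <- fx_scenario_from_matrix(matrix(1L, 64, 64))
  expect_equal(length(apply_habitat_loss(st, all_loss)$x), 0)
  # removal matches the destroyed-cell mask exactly
  sc <- generate_loss_map(0.08, 2 / 3, 64, seed = 2)
  ix <- floor(st$x * 64) + 1; iy <- floor(st$y * 64) + 1
  on_destroyed <- sc$loss_grid[cbind(ix, iy)] == 1
  pruned <- apply_habitat_loss(st, sc)
  expect_identical(pruned$id, st$id[!on_destroyed])
  # across loss seeds the removed fraction tracks the destroyed fraction
  fr <- vapply(1:5, function(s) {
    sci <- generate_loss_map(0.08, 2 / 3, 64, seed = s)
    1 - length(apply_habitat_loss(st, sci)$x) / length(st$x)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 2 / 3), 0.1)
})

test_that("individuals never occupy destroyed habitat after the loss event", {
  bi <- fx_burnin()
  sc <- generate_loss_map(0.1, 2 / 3, 64, seed = 3)
  cfg <- fx_cfg()
  tr <- run_scenario(bi$state, fx_landscape(), sc, cfg, delta_e = 0, seed = 4)
  st <- tr$state
  if (length(st$x) > 0) {
    ix <- floor(st$x * 64) + 1; iy <- floor(st$y * 64) + 1
    expect_true(all(sc$loss_grid[cbind(ix, iy)] == 0))
  }
  # displacement per accepted move is bounded by the uniform offsets
  expect_true(all(tr$census$mean_displacement <= sqrt(2) * cfg$sigma_p))
})

test_that("scenario runs follow the loss + change + post-change schedule", {
  bi <- fx_burnin()
  cfg <- fx_cfg()
  sc <- generate_loss_map(0.1, 2 / 3, 64, seed = 3)
  tr <- run_scenario(bi$state, fx_landscape(), sc, cfg, delta_e = 0, seed = 9)
  expect_s3_class(tr, "sim_trajectory")
  expect_equal(nrow(tr$census), cfg$change_duration + cfg$post_change)
  expect_equal(tr$pre$n, length(bi$state$x))
  # an extreme perturbation drives extinction before the end
  cfg_hard <- fx_cfg(sigma_f = 0.05)
  trh <- run_scenario(bi$state, fx_landscape(), sc, cfg_hard, delta_e = 10,
                      seed = 10)
  expect_equal(trh$census$n_alive[nrow(trh$census)], 0)
})
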