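test_that("generated landscapes are rescaled exactly to the target mean and SD", {
  for (s in 1:3) {
    L <- generate_landscape(landscape_params(mu_e = 2.5, sigma_e = 0.7,
                                             seed = s, resolution = 64))
    expect_equal(mean(L$grid), 2.5, tolerance = 1e-12)
    expect_equal(sd(L$grid), 0.7, tolerance = 1e-12)
  }
  # zero-variance scaling gives a constant grid at mu_e
  L0 <- generate_landscape(landscape_params(mu_e = 1.2, sigma_e = 0,
                                            seed = 1, resolution = 32))
  expect_true(all(L0$grid == 1.2))
})

test_that("landscape generation is deterministic under a fixed seed and validates inputs", {
  L1 <- generate_landscape(landscape_params(seed = 42, resolution = 32))
  L2 <- generate_landscape(landscape_params(seed = 42, resolution = 32))
  expect_identical(L1$grid, L2$grid)
  expect_error(landscape_params(resolution = 4), "resolution")
  expect_error(landscape_params(l_e = 0), "l_e")
  expect_error(landscape_params(sigma_e = -1), "sigma_e")
})

test_that("torus distance wraps per axis and maxes at sqrt(2)/2", {
  expect_equal(torus_distance(0.1, 0.1, 0.1, 0.1), 0)
  expect_equal(torus_distance(0.05, 0.5, 0.95, 0.5), 0.1)
  # symmetric
  expect_equal(torus_distance(0.9, 0.2, 0.1, 0.8),
               torus_distance(0.1, 0.8, 0.9, 0.2))
  # equals plain Euclidean whenever both separations are < 0.5
  set.seed(7)
  x1 <- runif(50, 0, 0.4); y1 <- runif(50, 0, 0.4)
  x2 <- x1 + runif(50, 0, 0.45); y2 <- y1 + runif(50, 0, 0.45)
  expect_equal(torus_distance(x1, y1, x2, y2),
               sqrt((x1 - x2)^2 + (y1 - y2)^2))
  # brute force over all pairs of a grid of points: max at opposite corners
  g <- expand.grid(x = (0:19) / 20, y = (0:19) / 20)
  dmax <- max(outer(seq_len(nrow(g)), seq_len(nrow(g)), function(i, j)
    torus_distance(g$x[i], g$y[i], g$x[j], g$y[j])))
  expect_equal(dmax, sqrt(2) / 2)
  # triangle inequality on random triples
  set.seed(8)
  for (k in 1:50) {
    p <- matrix(runif(6), 3, 2)
    d12 <- torus_distance(p[1, 1], p[1, 2], p[2, 1], p[2, 2])
    d23 <- torus_distance(p[2, 1], p[2, 2], p[3, 1], p[3, 2])
    d13 <- torus_distance(p[1, 1], p[1, 2], p[3, 1], p[3, 2])
    expect_lte(d13, d12 + d23 + 1e-12)
  }
})

test_that("Geary's C is ~1 for independent noise, <1 for autocorrelated fields, >1 for a checkerboard", {
  # null: iid grids, mean over replicates near 1
  set.seed(5)
  cs <- replicate(100, gearys_c(matrix(rnorm(32 * 32), 32, 32)))
  expect_gt(mean(cs), 0.95)
  expect_lt(mean(cs), 1.05)
  # 4x4 checkerboard: every rook pair differs by 1; the statistic reduces to
  # (N-1) * W / (2 W S) with S = N/4, i.e. 4 * 15/16 * ... = 1.875
  cb <- outer(1:4, 1:4, function(i, j) (i + j) %% 2)
  expect_equal(gearys_c(cb), 1.875)
  # strong positive autocorrelation
  expect_lt(fx_landscape(seed = 9, l_e = 0.2)$gearys_c, 1)
  # constant grid: undefined
  expect_error(gearys_c(matrix(1, 8, 8)), "constant")
})

test_that("mean Geary's C decreases with the autocorrelation length", {
  mean_c <- function(l_e) mean(vapply(1:20, function(s)
    generate_landscape(landscape_params(seed = s, l_e = l_e,
                                        resolution = 48))$gearys_c,
    numeric(1)))
  cs <- vapply(c(0.05, 0.1, 0.2), mean_c, numeric(1))
  expect_true(all(diff(cs) < 0))
})

test_that("the synthesized field has no seam: edge rows correlate like interior rows", {
  for (s in 1:5) {
    L <- generate_landscape(landscape_params(seed = s, l_e = 0.15,
                                             resolution = 64))
    g <- L$grid
    n <- nrow(g)
    # correlation of each row with its successor, including the wrap pair
    adj <- vapply(seq_len(n), function(i)
      cor(g[i, ], g[if (i == n) 1 else i + 1, ]), numeric(1))
    seam <- adj[n]
    interior <- adj[-n]
    expect_gt(seam, min(interior))
  }
})

test_that("environment lookup applies the warming ramp with per-generation increment delta_e/duration", {
  L <- fx_landscape()
  sched <- warming_schedule(delta_e = 3, duration = 100, start_gen = 50)
  raw <- env_at(L, 0.3, 0.7)
  # before the change: raw landscape value
  expect_equal(env_at(L, 0.3, 0.7, generation = 49, schedule = sched), raw)
  expect_equal(env_at(L, 0.3, 0.7, generation = 50, schedule = sched), raw)
  # one generation in: + delta_e/100
  expect_equal(env_at(L, 0.3, 0.7, generation = 51, schedule = sched),
               raw + 0.03)
  # at and after the end: + delta_e, held constant
  expect_equal(env_at(L, 0.3, 0.7, generation = 150, schedule = sched),
               raw + 3)
  expect_equal(env_at(L, 0.3, 0.7, generation = 400, schedule = sched),
               raw + 3)
  # coordinates wrap; destroyed cells give the NA sentinel
  expect_equal(env_at(L, 1.3, -0.3), env_at(L, 0.3, 0.7))
  full_loss <- fx_scenario_from_matrix(matrix(1, 64, 64))
  expect_true(is.na(env_at(L, 0.3, 0.7, scenario = full_loss)))
})

test_that("landscape CSV round-trips grid and parameters exactly", {
  L <- fx_landscape(seed = 21, resolution = 32)
  path <- withr::local_tempfile(fileext = ".csv")
  write_landscape(L, path)
  L2 <- read_landscape(path)
  expect_equal(L2$grid, L$grid)
  expect_equal(L2$params$l_e, L$params$l_e)
  expect_equal(L2$params$sigma_e, L$params$sigma_e)
})
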