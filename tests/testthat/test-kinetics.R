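# Decay kinetics: background subtraction, bootstrap medians, exponential
# fits, stratified half-lives and the growth-rate model.

chase_times <- c(0, 1, 2, 4, 8, 16, 32, 64)

test_that("background subtraction floors at zero and counts floored cells", {
  out <- background_subtract(c(100, 5, 30), 10)
  expect_equal(as.numeric(out), c(90, 0, 20))
  expect_equal(attr(out, "floored"), 1L)
  expect_warning(background_subtract(c(3, 4), 10), "all zero")
  expect_error(background_subtract(1:3, -1))
})

test_that("background subtraction removes the half-life bias it causes", {
  spec <- chase_spec(subpopulations = list(subpopulation("a", 1, 10)),
                     n_cells_per_timepoint = 500, background_level = 20,
                     seed = 14)
  d <- generate_chase(spec)
  biased <- estimate_half_life(d, bootstrap_config(seed = 2))
  d2 <- d
  d2$fluorescence <- as.numeric(background_subtract(d$fluorescence, 20))
  clean <- estimate_half_life(d2, bootstrap_config(seed = 2))
  expect_gt(biased$t_half, 1.3 * 10) # additive background biases long
  expect_equal(clean$t_half, 10, tolerance = 0.1)
})

test_that("bootstrap medians: constants, determinism, analytic spread", {
  const <- data.frame(time_min = rep(chase_times, each = 20),
                      fluorescence = 7)
  bm <- suppressWarnings(bootstrap_medians(const, bootstrap_config(seed = 1)))
  expect_true(all(bm$median_mean == 7))
  expect_true(all(bm$median_sd == 0))

  spec <- chase_spec(subpopulations = list(subpopulation("a", 1, 12)),
                     n_cells_per_timepoint = 600, seed = 10)
  d <- generate_chase(spec)
  b1 <- bootstrap_medians(d, bootstrap_config(seed = 4))
  b2 <- bootstrap_medians(d, bootstrap_config(seed = 4))
  expect_identical(b1, b2)
  expect_error(bootstrap_medians(d[0, ], bootstrap_config()), "empty")

  # lognormal population: bootstrap sd of the median vs the asymptotic
  # approximation sd = 1 / (2 f(m) sqrt(n))
  set.seed(5)
  x <- data.frame(time_min = 0, fluorescence = rlnorm(2000, log(100), 0.5))
  bm2 <- bootstrap_medians(x, bootstrap_config(n_rounds = 20,
                                               n_cells_per_round = 500,
                                               seed = 6))
  m <- median(x$fluorescence)
  f_m <- dnorm(log(m), log(100), 0.5) / m
  analytic <- 1 / (2 * f_m * sqrt(500))
  expect_gt(bm2$median_sd, analytic / 2)
  expect_lt(bm2$median_sd, analytic * 2)
})

test_that("fit_decay reproduces the closed form and flags non-decay", {
  y <- 100 * exp(-0.0693147 * chase_times)
  fit <- fit_decay(chase_times, y)
  expect_equal(fit$t_half, 10.0, tolerance = 1e-6)
  expect_identical(fit$t_half * fit$lambda, log(2))

  flat <- fit_decay(chase_times, rep(5, 8))
  expect_false(flat$decaying)
  expect_identical(flat$t_half, Inf)

  expect_error(fit_decay(c(0, 1), c(1, 0.5)))
})

test_that("t_half recovery within 10% at the printed half-lives (20 seeds)", {
  # full grid in the acceptance suite; here a representative pair
  for (th in c(4.6, 10.9)) {
    est <- vapply(1:20, function(s) {
      spec <- chase_spec(
        subpopulations = list(subpopulation("a", 1, th)),
        n_cells_per_timepoint = 500, cell_noise_cv = 0.3,
        seed = derive_seed(1000 + s, "recovery")
      )
      hl <- estimate_half_life(generate_chase(spec),
                               bootstrap_config(seed = s))
      hl$t_half
    }, numeric(1))
    expect_lt(abs(median(est) - th) / th, 0.10,
              label = sprintf("median recovery at t1/2 = %.1f", th))
  }
})

test_that("time-axis stretch scales the fitted half-life", {
  y <- 100 * exp(-log(2) / 9 * chase_times)
  f1 <- fit_decay(chase_times, y)
  f2 <- fit_decay(3 * chase_times, y)
  expect_equal(f2$t_half, 3 * f1$t_half, tolerance = 1e-6)
})

test_that("stratified half-lives separate and order the two strata", {
  spec <- chase_spec(
    subpopulations = list(subpopulation("free", 0.5, 4.6),
                          subpopulation("trapped", 0.5, 16.1, cluster = TRUE)),
    n_cells_per_timepoint = 500, seed = 19
  )
  d <- generate_chase(spec)
  st <- suppressWarnings(stratified_half_lives(d, bootstrap_config(seed = 3)))
  expect_lt(abs(st$non_cluster$t_half - 4.6) / 4.6, 0.15)
  expect_lt(abs(st$cluster$t_half - 16.1) / 16.1, 0.15)
  expect_gt(st$cluster$t_half, st$non_cluster$t_half)

  # shuffling the flags collapses the difference: both estimates land
  # between the two generating half-lives
  d_shuf <- d
  set.seed(23)
  d_shuf$cluster_flag <- sample(d_shuf$cluster_flag)
  sh <- suppressWarnings(stratified_half_lives(d_shuf, bootstrap_config(seed = 3)))
  for (f in sh) {
    expect_gt(f$t_half, 4.6)
    expect_lt(f$t_half, 16.1)
  }

  # null case: identical strata agree within 2 bootstrap sd
  spec0 <- chase_spec(
    subpopulations = list(subpopulation("x", 0.5, 10),
                          subpopulation("y", 0.5, 10, cluster = TRUE)),
    n_cells_per_timepoint = 500, seed = 29
  )
  st0 <- suppressWarnings(stratified_half_lives(generate_chase(spec0),
                                                bootstrap_config(seed = 7)))
  tol <- 2 * sqrt(st0$cluster$bootstrap_sd^2 + st0$non_cluster$bootstrap_sd^2)
  expect_lt(abs(st0$cluster$t_half - st0$non_cluster$t_half), tol)

  # a stratum missing a time point is skipped with a warning
  d_miss <- d[!(d$cluster_flag & d$time_min == 64), ]
  w <- capture_warnings(
    stm <- stratified_half_lives(d_miss, bootstrap_config(seed = 3))
  )
  expect_true(any(grepl("missing time point", w)))
  expect_null(stm$cluster)
  expect_false(is.null(stm$non_cluster))
})

test_that("the growth-rate model evaluates and fits exactly", {
  expect_equal(round(evaluate_growth_model(growth_model(-2.0, 0.1, 2.4), 0.55), 1),
               6.4)
  expect_equal(round(evaluate_growth_model(growth_model(-5.2, 3.3, 2.2), 0.55), 1),
               11.5)
  expect_equal(evaluate_growth_model(growth_model(0, 0, 1.7), c(0, 1, 5)),
               rep(exp(1.7), 3))

  mu <- c(0.11, 0.51, 0.80)
  th <- exp(-2.3 * mu^2 + 0.6 * mu + 2.7)
  gm <- fit_growth_model(mu, th)
  expect_equal(gm$a, -2.3, tolerance = 1e-6)
  expect_equal(gm$b, 0.6, tolerance = 1e-6)
  expect_equal(gm$c, 2.7, tolerance = 1e-6)

  flat <- fit_growth_model(c(0.1, 0.4, 0.9), rep(exp(2), 3))
  expect_equal(flat$a, 0, tolerance = 1e-9)
  expect_equal(flat$b, 0, tolerance = 1e-9)
  expect_equal(flat$c, 2, tolerance = 1e-9)

  expect_error(fit_growth_model(c(0.1, 0.1, 0.1), c(5, 5, 5)), "distinct")

  set.seed(8)
  mu10 <- seq(0.1, 1, length.out = 10)
  noise_sd <- 0.05
  th10 <- exp(-2.3 * mu10^2 + 0.6 * mu10 + 2.7 + rnorm(10, 0, noise_sd))
  gm10 <- fit_growth_model(mu10, th10)
  pred <- log(evaluate_growth_model(gm10, mu10))
  rmse <- sqrt(mean((pred - (-2.3 * mu10^2 + 0.6 * mu10 + 2.7))^2))
  expect_lt(rmse, 2 * noise_sd)
})

test_that("bootstrap pipeline is reproducible and stable across seeds", {
  spec <- chase_spec(subpopulations = list(subpopulation("a", 1, 8)),
                     n_cells_per_timepoint = 500, seed = 33)
  d <- generate_chase(spec)
  h1 <- estimate_half_life(d, bootstrap_config(seed = 12))
  h2 <- estimate_half_life(d, bootstrap_config(seed = 12))
  expect_identical(h1$t_half, h2$t_half)
  others <- vapply(13:17, function(s) {
    estimate_half_life(d, bootstrap_config(seed = s))$t_half
  }, numeric(1))
  expect_true(all(abs(others - h1$t_half) < 3 * pmax(h1$bootstrap_sd, 1e-3)))
})
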