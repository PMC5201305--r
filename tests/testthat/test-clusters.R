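# Polar-cluster classification and population statistics.

make_cell_spots <- function(I, v, w = 3, u = 0) {
  data.frame(u = u, v = v, w = w, I = I)
}

test_that("the three-condition cluster rule behaves as specified", {
  cfg <- cluster_config()
  # ten equal dim spots: no spot holds >= 50% of the total
  dim10 <- make_cell_spots(I = rep(10, 10), v = seq(50, 860, length.out = 10))
  expect_false(classify_cell(dim10, sum(dim10$I), cfg)$has_cluster)

  # compact bright polar spot holding 60% of the signal
  pol <- make_cell_spots(I = c(60, 20, 20), v = c(800, 200, 350))
  res <- classify_cell(pol, 100, cfg)
  expect_true(res$has_cluster)
  expect_equal(res$cluster$I, 60)

  # bright but not polar
  mid <- make_cell_spots(I = c(60, 40), v = c(0.3 * 900, 100))
  expect_false(classify_cell(mid, 100, cfg)$has_cluster)

  # bright, polar, but not compact
  wide <- make_cell_spots(I = c(60, 40), v = c(800, 100), w = c(9, 3))
  expect_false(classify_cell(wide, 100, cfg)$has_cluster)

  # zero total intensity -> negative
  expect_false(classify_cell(pol, 0, cfg)$has_cluster)
})

test_that("raising a qualifying spot's intensity never flips positive to negative", {
  cfg <- cluster_config()
  base <- make_cell_spots(I = c(55, 45), v = c(700, 100))
  stopifnot(classify_cell(base, 100, cfg)$has_cluster)
  for (mult in c(1.5, 3, 10)) {
    up <- base
    up$I[1] <- base$I[1] * mult
    total <- sum(up$I)
    expect_true(classify_cell(up, total, cfg)$has_cluster,
                label = sprintf("x%g intensity", mult))
  }
})

test_that("synthetic polar-cluster cells classify positive, uniform negative", {
  model <- model_cell()
  cfg <- cluster_config()
  sc <- generate_scene(scene_spec(n_cells = 200, pattern = "polar_cluster",
                                  seed = 71), render = FALSE)
  ns <- normalize_spots(sc$truth$spots, sc$truth$cells, model)
  totals <- data.frame(cell_id = sc$truth$cells$cell_id,
                       total_I = sc$truth$cells$total_I)
  cls <- classify_cells(ns, totals, cfg, model)
  expect_gte(mean(cls$has_cluster), 0.9)

  scu <- generate_scene(scene_spec(n_cells = 200, pattern = "uniform",
                                   seed = 72), render = FALSE)
  nsu <- normalize_spots(scu$truth$spots, scu$truth$cells, model)
  totu <- data.frame(cell_id = scu$truth$cells$cell_id,
                     total_I = scu$truth$cells$total_I)
  clsu <- classify_cells(nsu, totu, cfg, model)
  expect_lte(mean(clsu$has_cluster), 0.05)
})

test_that("cluster fraction estimates are unbiased for the mixture probability", {
  model <- model_cell()
  cfg <- cluster_config()
  p_true <- 0.4
  n <- 500
  sc_pos <- generate_scene(scene_spec(n_cells = round(p_true * n),
                                      pattern = "polar_cluster", seed = 81),
                           render = FALSE)
  sc_neg <- generate_scene(scene_spec(n_cells = n - round(p_true * n),
                                      pattern = "uniform", seed = 82),
                           render = FALSE)
  est <- numeric(0)
  for (sc in list(sc_pos, sc_neg)) {
    ns <- normalize_spots(sc$truth$spots, sc$truth$cells, model)
    tot <- data.frame(cell_id = sc$truth$cells$cell_id,
                      total_I = sc$truth$cells$total_I)
    est <- c(est, classify_cells(ns, tot, cfg, model)$has_cluster)
  }
  p_hat <- mean(est)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 2 * se)
})

test_that("cluster fraction by level reports binomial fractions and SEs", {
  all_pos <- data.frame(level = runif(100, 1, 50), has_cluster = TRUE)
  tab <- cluster_fraction_by_level(all_pos, n_bins = 5)
  expect_true(all(tab$fraction == 1))
  expect_true(all(tab$se == 0))

  set.seed(61)
  lev <- rgamma(2000, shape = 1.2, scale = 8)
  cells <- data.frame(
    level = lev,
    has_cluster = runif(2000) < ifelse(lev > 10, 0.8, 0.05)
  )
  tab2 <- cluster_fraction_by_level(cells, breaks = c(0, 5, 10, 20, 100))
  below <- tab2[tab2$bin_hi <= 10, ]
  above <- tab2[tab2$bin_lo >= 10, ]
  expect_true(all(abs(below$fraction - 0.05) <= 3 * pmax(below$se, 0.011)))
  expect_true(all(abs(above$fraction - 0.80) <= 3 * above$se))

  expect_warning(
    one <- cluster_fraction_by_level(
      data.frame(level = c(1, 100), has_cluster = c(TRUE, FALSE)),
      breaks = c(0, 50, 200)
    ),
    "single cell"
  )
  expect_true(all(one$se == 0))
  expect_equal(nrow(cluster_fraction_by_level(all_pos[0, ])), 0L)
})

test_that("gamma fits recover known parameters", {
  set.seed(303)
  x <- rgamma(1e4, shape = 2, scale = 3)
  fit <- fit_expression_gamma(x)
  expect_equal(fit$shape, 2, tolerance = 0.05)
  expect_equal(fit$scale, 3, tolerance = 0.05)

  ex <- rgamma(1e4, shape = 1, scale = 5) # exponential special case
  expect_equal(fit_expression_gamma(ex)$shape, 1, tolerance = 0.05)

  expect_error(fit_expression_gamma(rgamma(5, 2, 1)), "at least 10")
  expect_error(fit_expression_gamma(rep(4, 100)), "all levels equal")

  # scale recovery across shapes
  for (shape in c(0.5, 1, 2, 5)) {
    y <- rgamma(1e4, shape = shape, scale = 2.5)
    f <- fit_expression_gamma(y)
    expect_equal(f$scale, 2.5, tolerance = 0.1,
                 label = sprintf("scale at shape %.1f", shape))
  }

  # zeros are excluded and recorded
  withz <- c(rgamma(1000, 2, 1), rep(0, 250))
  fz <- fit_expression_gamma(withz)
  expect_equal(fz$zero_fraction, 0.2)
  expect_equal(fz$n_cells, 1000)
})

test_that("FWHM / reciprocal-intensity heat maps behave under scaling", {
  one <- data.frame(w = 3, I = 100)
  hm <- fwhm_intensity_heatmap(one, fwhm_range = c(2, 4),
                               inv_i_range = c(0, 0.05), n_bins = 10)
  expect_equal(sum(hm$counts), 1)
  expect_equal(sum(hm$counts > 0), 1)

  set.seed(11)
  spots <- data.frame(w = runif(200, 2, 4), I = runif(200, 50, 500))
  h1 <- fwhm_intensity_heatmap(spots, fwhm_range = c(2, 4),
                               inv_i_range = c(0, 0.02), n_bins = 20)
  spots2 <- spots
  spots2$I <- 2 * spots$I
  h2 <- fwhm_intensity_heatmap(spots2, fwhm_range = c(2, 4),
                               inv_i_range = c(0, 0.01), n_bins = 20)
  expect_equal(h2$counts, h1$counts) # halved reciprocals, halved range

  # cluster spots occupy lower 1/I than dim uniform spots at similar FWHM
  sc <- generate_scene(scene_spec(n_cells = 100, pattern = "polar_cluster",
                                  seed = 55), render = FALSE)
  sp <- sc$truth$spots
  expect_lt(median(1 / sp$I[sp$is_cluster]), median(1 / sp$I[!sp$is_cluster]))

  expect_warning(fwhm_intensity_heatmap(data.frame(w = c(3, 3), I = c(10, 0))),
                 "excluded")
})

test_that("focus-to-cluster distances and their normal fit", {
  f <- data.frame(cell_id = c(1, 2), x = c(0, 0), y = c(0, 300))
  cl <- data.frame(cell_id = c(1, 2, 3), x = c(0, 0, 5), y = c(0, 700, 5))
  ds <- foci_distances(f, cl)
  expect_equal(sort(ds$distances), c(0, 400))
  expect_equal(ds$n_skipped, 1L)

  set.seed(77)
  n <- 500
  fx <- rnorm(n, 0, 1)
  d_true <- rnorm(n, 400, 80)
  f2 <- data.frame(cell_id = seq_len(n), x = fx, y = 0)
  c2 <- data.frame(cell_id = seq_len(n), x = fx, y = d_true)
  ds2 <- foci_distances(f2, c2)
  expect_lt(abs(ds2$mean - 400), 3 * 80 / sqrt(n))
  expect_equal(ds2$sd, 80, tolerance = 0.15)
})

test_that("spread ratio measures profile confinement", {
  expect_equal(spread_ratio(rep(5, 40)), 1.0)
  central <- c(rep(0, 10), rep(8, 20), rep(0, 10))
  expect_equal(spread_ratio(central), 0.5)
  expect_error(spread_ratio(rep(0, 10)), "flat")

  # bimodal (nucleoid-excluded) vs uniform: threshold crossing the dip
  x <- seq(0, 1, length.out = 100)
  bimodal <- dnorm(x, 0.25, 0.07) + dnorm(x, 0.75, 0.07)
  expect_lt(spread_ratio(bimodal, threshold_fraction = 0.5),
            spread_ratio(rep(1, 100), threshold_fraction = 0.5))
})
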