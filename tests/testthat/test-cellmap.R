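# Model-cell projection: frames, normalization, location maps, axial
# profiles, zone classification.

test_that("cell_frame recovers orientation, length and width", {
  cap <- capsule_polygon(20, 10)
  fr <- cell_frame(cap)
  ang <- abs(atan2(fr$axis[2], fr$axis[1])) %% pi
  expect_lt(min(ang, pi - ang), pi / 180)
  expect_equal(fr$length, 20, tolerance = 1e-3)
  expect_equal(fr$width, 10, tolerance = 1e-3)

  rot <- transform_polygon(cap, 30 * pi / 180, c(5, -3))
  fr2 <- cell_frame(rot)
  ang2 <- atan2(fr2$axis[2], fr2$axis[1]) %% pi
  expect_lt(min(abs(ang2 - 30 * pi / 180), pi - abs(ang2 - 30 * pi / 180)),
            pi / 180)
  expect_equal(fr2$centroid, c(5, -3), tolerance = 1e-6)

  circ <- capsule_polygon(10, 10 - 1e-9, n_arc = 90)
  frc <- cell_frame(circ)
  expect_equal(frc$length / frc$width, 1, tolerance = 0.02)

  expect_error(cell_frame(cbind(c(0, 1, 2), c(0, 1, 2))), "degenerate")
})

test_that("normalize_spot maps centroid to origin and pole apex to (0, 900)", {
  cap <- transform_polygon(capsule_polygon(24, 10), 0.4, c(100, 50))
  fr <- cell_frame(cap)
  mid <- normalize_spot(100, 50, fr, model_cell())
  expect_equal(mid$u, 0, tolerance = 1e-6)
  expect_equal(mid$v, 0, tolerance = 1e-6)

  apex <- c(100 + 12 * cos(0.4), 50 + 12 * sin(0.4))
  pole <- normalize_spot(apex[1], apex[2], fr, model_cell())
  expect_equal(pole$u, 0, tolerance = 1e-4)
  expect_equal(pole$v, 900, tolerance = 0.5)
})

test_that("projection is idempotent for an already-model-scaled cell", {
  model <- model_cell()
  cap <- capsule_polygon(1800, 800) # nm, model-sized, axis-aligned at origin
  fr <- cell_frame(cap)
  pts <- rbind(c(300, 120), c(-700, -250), c(820, 0))
  for (i in seq_len(nrow(pts))) {
    nv <- normalize_spot(pts[i, 1], pts[i, 2], fr, model)
    expect_equal(nv$v, abs(pts[i, 1]), tolerance = 2e-3)
    expect_equal(abs(nv$u), abs(pts[i, 2]), tolerance = 2e-3)
  }
})

test_that("membrane-pattern spots land in the membrane band", {
  sc <- generate_scene(scene_spec(n_cells = 200, pattern = "membrane",
                                  spots_per_cell_mean = 5, seed = 17),
                       render = FALSE)
  ns <- normalize_spots(sc$truth$spots, sc$truth$cells)
  expect_gte(nrow(ns), 1000)
  zones <- zone_classify(ns$u, ns$v)
  expect_gte(mean(zones == "membrane"), 0.9)
})

test_that("location maps conserve counts and localize polar clusters", {
  model <- model_cell()
  one <- data.frame(cell_id = 1, u = 55, v = 432, I = 3)
  m1 <- build_location_map(one, model, smooth_nm = 0)
  expect_equal(sum(m1$counts), 1)
  expect_equal(sum(m1$counts > 0), 1)

  for (pat in c("uniform", "membrane", "polar_cluster")) {
    for (seed in c(1, 7)) {
      sc <- generate_scene(scene_spec(n_cells = 60, pattern = pat, seed = seed),
                           render = FALSE)
      ns <- normalize_spots(sc$truth$spots, sc$truth$cells, model)
      m <- build_location_map(ns, model)
      expect_equal(sum(m$counts), nrow(ns),
                   label = sprintf("mass conservation (%s, seed %d)", pat, seed))
    }
  }

  sc <- generate_scene(scene_spec(n_cells = 300, pattern = "polar_cluster",
                                  seed = 5), render = FALSE)
  ns <- normalize_spots(sc$truth$spots, sc$truth$cells, model)
  m <- build_location_map(ns, model, weight = "intensity")
  peak <- which(m$density == max(m$density), arr.ind = TRUE)
  v_peak <- (m$v_breaks[peak[1, 2]] + m$v_breaks[peak[1, 2] + 1]) / 2
  expect_gt(v_peak, 0.6 * model$half_length_nm)

  expect_error(build_location_map(one, model, bin_nm = 5000), "larger")
})

test_that("axial profiles discriminate uniform from polar patterns", {
  model <- model_cell()
  sc <- generate_scene(scene_spec(n_cells = 1500, pattern = "uniform",
                                  spots_per_cell_mean = 8, seed = 12),
                       render = FALSE)
  ns <- normalize_spots(sc$truth$spots, sc$truth$cells, model)
  expect_gte(nrow(ns), 1e4)
  m <- build_location_map(ns, model, smooth_nm = 0)
  prof <- axial_profile(m, use = "counts")
  # drop the partial-area apex bins; the rest should be flat
  body <- prof$value[prof$v < 850]
  expect_lt(sd(body) / mean(body), 0.2)

  scp <- generate_scene(scene_spec(n_cells = 200, pattern = "polar_cluster",
                                   seed = 13), render = FALSE)
  nsp <- normalize_spots(scp$truth$spots, scp$truth$cells, model)
  mp <- build_location_map(nsp, model, weight = "intensity")
  pp <- axial_profile(mp)
  expect_gt(pp$v[which.max(pp$value)], 0.6 * model$half_length_nm)

  single <- data.frame(cell_id = 1, u = 0, v = 455, I = 1)
  ms <- build_location_map(single, model, smooth_nm = 0)
  ps <- axial_profile(ms, use = "counts")
  expect_equal(ps$v[which(ps$value > 0)], 462.5) # bin containing v = 455
  expect_equal(sum(ps$value > 0), 1)
})

test_that("zone classification applies the stated precedence", {
  model <- model_cell()
  expect_equal(as.character(zone_classify(0, 0, model)), "nucleoid")
  expect_equal(as.character(zone_classify(0, 900, model)), "membrane")
  expect_equal(as.character(zone_classify(0, 800, model)), "pole")
  expect_equal(as.character(zone_classify(390, 100, model)), "membrane")
  expect_equal(as.character(zone_classify(300, 200, model)), "cytoplasm")
})

test_that("patterns are separated by zone fractions", {
  model <- model_cell()
  zf <- list()
  for (pat in c("membrane", "polar_cluster", "uniform",
                "cytoplasmic_nucleoid_excluded")) {
    sc <- generate_scene(scene_spec(n_cells = 500, pattern = pat, seed = 23),
                         render = FALSE)
    ns <- normalize_spots(sc$truth$spots, sc$truth$cells, model)
    zf[[pat]] <- list(count = zone_fractions(ns, model),
                      signal = zone_fractions(ns, model, weight = "intensity"))
  }
  mem_count <- vapply(zf, function(z) z$count[["membrane"]], numeric(1))
  expect_equal(names(which.max(mem_count)), "membrane")
  pole_count <- vapply(zf[c("membrane", "polar_cluster", "uniform")],
                       function(z) z$count[["pole"]], numeric(1))
  expect_equal(names(which.max(pole_count)), "polar_cluster")
  # signal-weighted fractions separate all four patterns at the pole
  pole_signal <- vapply(zf, function(z) z$signal[["pole"]], numeric(1))
  expect_equal(names(which.max(pole_signal)), "polar_cluster")
  expect_equal(zf$cytoplasmic_nucleoid_excluded$count[["nucleoid"]], 0)
})
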