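# Generator contracts: determinism, ground-truth fidelity, and the
# statistical structure the generators declare.

test_that("generators are bit-identical under a fixed seed", {
  a <- gen_cell_image(semi_minor_um = 8, nucleus_offset_um = 2, nucleus_radius_um = 2.5, pixel_size = 0.5, img_px = 96, seed = 7)
  b <- gen_cell_image(semi_minor_um = 8, nucleus_offset_um = 2, nucleus_radius_um = 2.5, pixel_size = 0.5, img_px = 96, seed = 7)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$cell_mask$coords, b$cell_mask$coords)
  c2 <- gen_cell_image(semi_minor_um = 8, nucleus_offset_um = 2, nucleus_radius_um = 2.5, pixel_size = 0.5, img_px = 96, seed = 8)
  expect_false(identical(a$image$pixels, c2$image$pixels))

  fa1 <- gen_fa_image(seed = 3); fa2 <- gen_fa_image(seed = 3)
  expect_identical(fa1$image$pixels, fa2$image$pixels)
  expect_identical(fa1$truth$centers_xy, fa2$truth$centers_xy)

  t1 <- gen_tracks(n_cells = 4, n_steps = 12, seed = 5)
  t2 <- gen_tracks(n_cells = 4, n_steps = 12, seed = 5)
  expect_identical(t1$tracks$x, t2$tracks$x)

  d1 <- gen_detachment_counts(seed = 2); d2 <- gen_detachment_counts(seed = 2)
  expect_identical(d1$counts, d2$counts)

  m1 <- gen_mtoc_cells(n = 50, seed = 2); m2 <- gen_mtoc_cells(n = 50, seed = 2)
  expect_identical(m1$cells, m2$cells)
})

test_that("generators do not disturb the global RNG stream", {
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(gen_cell_image(semi_minor_um = 8, nucleus_offset_um = 2, nucleus_radius_um = 2.5, pixel_size = 0.5,
                                          img_px = 96, seed = 1))
  expect_identical(runif(1), before)
})

test_that("cell generator geometry honours its stated parameters", {
  # zero offset, zero noise: perfectly symmetric cell, zero polarity
  g0 <- gen_cell_image(nucleus_offset_um = 0, noise_sd = 0,
                       semi_minor_um = 8, pixel_size = 0.5, img_px = 97,
                       seed = 1)
  expect_equal(polarity_distance(g0$record), 0)
  # noiseless image has exactly two intensity levels
  expect_setequal(unique(as.numeric(g0$image$pixels)), c(100, 220))
  # nucleus stays inside the cell; infeasible offsets error
  expect_true(mask_is_subset(g0$nucleus_mask, g0$cell_mask))
  expect_error(gen_cell_image(nucleus_offset_um = 18, semi_minor_um = 8,
                              pixel_size = 0.5, img_px = 96),
               "outside the cell")
})

test_that("orientation round-trips through the mask pipeline", {
  g <- gen_cell_image(orientation_deg = 30, axis_ratio = 2, seed = 2)
  a <- frontline_angle(min_bounding_rect(g$cell_mask),
                       g$truth$frontline_direction)
  expect_lt(abs(a - 30), 2)
})

test_that("fa generator enforces spacing and reports infeasible packings", {
  g <- gen_fa_image(n_puncta = 12, min_spacing_px = 10, seed = 1)
  d <- as.matrix(stats::dist(g$truth$centers_xy))
  diag(d) <- Inf
  expect_gte(min(d), 10)
  expect_error(gen_fa_image(n_puncta = 500, min_spacing_px = 30,
                            max_attempts = 2000, seed = 1), "infeasible")
})

test_that("track persistence limits behave as declared", {
  hi <- gen_tracks(n_cells = 10, n_steps = 40, persistence = 0.999, seed = 3)
  expect_gt(mean(track_stats_all(hi$tracks)$directionality), 0.99)
  expect_error(gen_tracks(persistence = 1), "persistence")
  expect_error(gen_tracks(persistence = -0.1), "persistence")
})

test_that("step-angle autocorrelation at lag 1 equals the persistence", {
  p <- 0.6
  g <- gen_tracks(n_cells = 300, n_steps = 40, persistence = p, seed = 13)
  cors <- unlist(lapply(split(g$tracks, g$tracks$cell_id), function(tr) {
    ang <- atan2(diff(tr$y), diff(tr$x))
    cos(diff(ang))
  }))
  sem <- stats::sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors) - p), 4 * sem)
})

test_that("biased walks drift along the bias direction", {
  g <- gen_tracks(n_cells = 60, n_steps = 40, persistence = 0.2,
                  bias_direction = c(0, 1), bias_strength = 1, seed = 21)
  ends <- do.call(rbind, lapply(split(g$tracks, g$tracks$cell_id), function(tr) {
    c(tail(tr$x, 1) - tr$x[1], tail(tr$y, 1) - tr$y[1])
  }))
  expect_gt(mean(ends[, 2]), 3 * stats::sd(ends[, 2]) / sqrt(nrow(ends)))
})

test_that("detachment generator matches its closed-form expectation", {
  g <- gen_detachment_counts(n_cells = 5000, rate_per_min = 0.5,
                             times_min = c(5), seed = 6)
  frac <- detachment_fraction(g$counts$detached, g$counts$residual)
  expect_lt(abs(frac - (1 - exp(-2.5))), 3 * sqrt(0.08 * 0.92 / 5000))
  # limits: t = 0 gives 0; a huge rate saturates
  g0 <- gen_detachment_counts(n_cells = 100, rate_per_min = 1,
                              times_min = c(0), seed = 1)
  expect_equal(g0$counts$detached, 0)
  gsat <- gen_detachment_counts(n_cells = 100, rate_per_min = 50,
                                times_min = c(5), seed = 1)
  expect_equal(gsat$counts$detached, 100)
})

test_that("spheroid masks are concentric and ordered", {
  g <- gen_spheroid_masks(10, 25)
  expect_true(mask_is_subset(g$core_mask, g$total_mask))
  geq <- gen_spheroid_masks(12, 12)
  expect_equal(dispersal_ratio(geq$total_mask, geq$core_mask, 1)$ratio, 1)
  expect_error(gen_spheroid_masks(20, 10), "total_radius_px >= core_radius_px")
})
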