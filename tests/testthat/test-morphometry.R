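# Per-cell geometry and intensity measures.

test_that("cell_area scales pixel counts by the calibration", {
  expect_equal(cell_area(rect_mask(1, 1, 10, 20, c(30, 30)), 0.5), 50)
  expect_equal(cell_area(region_mask(cbind(5, 5), c(10, 10)), 1), 1)
  # digital disk against brute-force enumeration
  cc <- expand.grid(row = 1:50, col = 1:50)
  inside <- (cc$col - 25)^2 + (cc$row - 25)^2 <= 20^2
  disk <- region_mask(cbind(cc$row[inside], cc$col[inside]), c(50, 50))
  expect_equal(cell_area(disk, 1), oracle_disk_pixel_count(25, 25, 20, 50, 50))
})

test_that("polarity distance is the nucleus-to-centroid offset in um", {
  cell <- rect_mask(1, 1, 21, 21, c(25, 25))
  nuc <- rect_mask(10, 10, 12, 12, c(25, 25))  # same centroid (11, 11)
  expect_equal(polarity_distance(cell, nuc, 1), 0)

  row_cell <- rect_mask(5, 1, 5, 21, c(10, 25))
  left_px <- region_mask(cbind(5, 1), c(10, 25))
  expect_equal(polarity_distance(row_cell, left_px, 1), 10)

  g <- gen_cell_image(nucleus_offset_um = 3, semi_minor_um = 8,
                      nucleus_radius_um = 2.5, pixel_size = 0.5,
                      img_px = 96, seed = 1)
  expect_lt(abs(polarity_distance(g$record) - 3), 0.5)  # within 1 px
})

test_that("intensity stats subtract the background mean", {
  img <- image_plane(matrix(10, 40, 40), 1)
  img$pixels[11:20, 11:15] <- 100           # 50-px cell at 100
  cell <- rect_mask(11, 11, 20, 15, c(40, 40))
  bg <- rect_mask(30, 30, 35, 35, c(40, 40))
  s <- intensity_stats(cell, img, bg)
  expect_equal(s$mean_intensity, 90)
  expect_equal(s$total_intensity, 4500)
  expect_equal(s$total_intensity, s$mean_intensity * mask_size(cell))

  flat <- image_plane(matrix(10, 40, 40), 1)
  s0 <- intensity_stats(cell, flat, bg)
  expect_equal(s0$mean_intensity, 0)
  expect_equal(s0$total_intensity, 0)

  # invariant to a common offset
  img2 <- image_plane(img$pixels + 37, 1)
  s2 <- intensity_stats(cell, img2, bg)
  expect_equal(s2$mean_intensity, s$mean_intensity)

  expect_error(intensity_stats(cell, img, cell), "overlap")
})

test_that("amplitude is recovered from synthetic cells within noise", {
  g <- gen_cell_image(tubulin_amplitude = 120, noise_sd = 6,
                      semi_minor_um = 8, nucleus_offset_um = 2,
                      nucleus_radius_um = 2.5, pixel_size = 0.5, img_px = 96,
                      seed = 11)
  bg <- rect_mask(2, 2, 13, 13, c(96, 96))
  s <- intensity_stats(g$cell_mask, g$image, bg)
  sem <- sqrt((6^2 + 1 / 12) * (1 / mask_size(g$cell_mask) + 1 / mask_size(bg)))
  expect_lt(abs(s$mean_intensity - 120), 3 * sem)
})

test_that("min_bounding_rect handles axis-aligned bars and rotations", {
  m <- matrix(FALSE, 30, 30); m[10:13, 5:14] <- TRUE   # 4 rows x 10 cols
  r <- min_bounding_rect(matrix_to_mask(m))
  expect_equal(r$long_edge_length, 9)   # pixel-centre extent
  expect_equal(r$short_edge_length, 3)
  expect_equal(abs(r$long_edge_direction), c(x = 1, y = 0))

  r2 <- min_bounding_rect(matrix_to_mask(t(m)))
  expect_equal(r2$long_edge_length, 9)
  expect_equal(abs(r2$long_edge_direction), c(x = 0, y = 1))

  expect_error(min_bounding_rect(region_mask(cbind(1:5, 3), c(9, 9))),
               "collinear")
})

test_that("minimal rectangle area matches the exhaustive oracle", {
  withr::local_seed(42)
  for (i in 1:30) {
    pts <- random_point_cloud(30)
    r <- min_bounding_rect(pts)
    expect_equal(r$area, oracle_min_rect_area(pts), tolerance = 1e-12)
    # never larger than the axis-aligned bounding box
    expect_lte(r$area,
               diff(range(pts[, 1])) * diff(range(pts[, 2])) + 1e-12)
  }
})

test_that("frontline angle follows the fold-to-[0,90] convention", {
  fd <- c(1, 0)  # travel to the right; frontline axis vertical
  vert <- min_bounding_rect(matrix_to_mask({
    m <- matrix(FALSE, 30, 30); m[5:24, 10:12] <- TRUE; m
  }))
  expect_equal(frontline_angle(vert, fd), 0)
  horiz <- min_bounding_rect(matrix_to_mask({
    m <- matrix(FALSE, 30, 30); m[10:12, 5:24] <- TRUE; m
  }))
  expect_equal(frontline_angle(horiz, fd), 90)
  expect_equal(frontline_angle(horiz, fd, complement = TRUE), 0)

  # long edge at 135 degrees to the frontline axis folds to 45
  u <- c(sin(135 * pi / 180), cos(135 * pi / 180))
  v <- c(-u[2], u[1])
  grid <- expand.grid(s = seq(0, 20, by = 0.5), t = 0:2)
  pts <- cbind(grid$s * u[1] + grid$t * v[1], grid$s * u[2] + grid$t * v[2])
  expect_equal(frontline_angle(min_bounding_rect(pts), fd), 45,
               tolerance = 1e-9)
})

test_that("rotating a mask by 90 degrees maps the angle to its complement", {
  withr::local_seed(7)
  for (th in c(10, 35, 70)) {
    g <- gen_cell_image(orientation_deg = th, semi_minor_um = 8,
                        nucleus_offset_um = 2, nucleus_radius_um = 2.5,
                        pixel_size = 0.5, img_px = 96, seed = th)
    m <- mask_to_matrix(g$cell_mask)
    a1 <- frontline_angle(min_bounding_rect(g$cell_mask), c(1, 0))
    rot <- matrix_to_mask(t(m)[, nrow(m):1, drop = FALSE])  # 90-degree rotation
    a2 <- frontline_angle(min_bounding_rect(rot), c(1, 0))
    expect_equal(a2, 90 - a1, tolerance = 1e-8)
    expect_equal(mask_size(rot), mask_size(g$cell_mask))
  }
})

test_that("a square bounding rectangle reports 0 with a warning", {
  sq <- rect_mask(1, 1, 5, 5, c(10, 10))
  r <- min_bounding_rect(sq)
  expect_true(r$square)
  expect_warning(a <- frontline_angle(r, c(1, 0)), "square")
  expect_equal(a, 0)
})

test_that("measure_cell assembles the five per-cell measures", {
  g <- gen_cell_image(orientation_deg = 20, semi_minor_um = 8,
                      nucleus_offset_um = 3, nucleus_radius_um = 2.5,
                      pixel_size = 0.5, img_px = 96, seed = 3)
  bg <- rect_mask(2, 2, 13, 13, c(96, 96))
  res <- measure_cell(g$record, bg)
  expect_named(res, c("area_um2", "polarity_um", "total_intensity",
                      "mean_intensity", "total_intensity_raw",
                      "mean_intensity_raw", "angle_deg"))
  expect_equal(res$area_um2, cell_area(g$cell_mask, 0.5))
  expect_gte(res$angle_deg, 0)
  expect_lte(res$angle_deg, 90)
  expect_equal(res$total_intensity, res$mean_intensity * mask_size(g$cell_mask))
})
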