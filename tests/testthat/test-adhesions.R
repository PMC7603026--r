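# Focal-adhesion punctum detection, metrics, and object counting.

test_that("connected-component labeling matches EBImage (4-connectivity)", {
  skip_if_not_installed("EBImage")
  withr::local_seed(5)
  for (i in 1:10) {
    bw <- matrix(runif(40 * 40) < 0.3, 40, 40)
    ours <- label_components(bw, connectivity = 4)
    ref <- EBImage::bwlabel(bw * 1)
    expect_equal(max(ours), max(ref))
    # same partition: each of our components maps to exactly one reference label
    for (k in seq_len(max(ours)))
      expect_length(unique(ref[ours == k]), 1)
  }
})

test_that("8-connectivity joins diagonals, 4-connectivity does not", {
  bw <- matrix(FALSE, 5, 5); bw[1, 1] <- TRUE; bw[2, 2] <- TRUE
  expect_equal(max(label_components(bw, 8)), 1)
  expect_equal(max(label_components(bw, 4)), 2)
})

make_puncta_image <- function(centers, radius = 3, amp = 200, bg = 10,
                              dim = c(80, 80)) {
  px <- matrix(bg, dim[1], dim[2])
  cc <- expand.grid(row = seq_len(dim[1]), col = seq_len(dim[2]))
  for (i in seq_len(nrow(centers))) {
    d <- (cc$col - centers[i, 1])^2 + (cc$row - centers[i, 2])^2 <= radius^2
    px[cbind(cc$row[d], cc$col[d])] <- bg + amp
  }
  image_plane(px, 1, "vinculin")
}

test_that("disjoint bright disks are each detected once", {
  centers <- cbind(c(15, 35, 55, 25, 60), c(15, 20, 15, 55, 55))
  img <- make_puncta_image(centers)
  cell <- rect_mask(5, 5, 75, 75, c(80, 80))
  bg <- rect_mask(1, 1, 3, 80, c(80, 80))
  ps <- detect_puncta(img, cell, bg, rel_threshold = 0.5, min_area_px = 4)
  expect_length(ps$regions, 5)

  flat <- image_plane(matrix(10, 80, 80), 1)
  expect_length(detect_puncta(flat, cell, bg)$regions, 0)
})

test_that("planted puncta are recovered with oracle-exact areas", {
  g <- gen_fa_image(n_puncta = 12, radius_px = 3, min_spacing_px = 10, seed = 6)
  bg <- rect_mask(1, 1, 12, 12, c(192, 192))
  ps <- detect_puncta(g$image, g$cell_mask, bg)
  expect_length(ps$regions, 12)
  detected_px <- sort(vapply(ps$regions, mask_size, 0L))
  oracle_px <- sort(vapply(seq_len(12), function(i) {
    oracle_disk_pixel_count(g$truth$centers_xy[i, 1], g$truth$centers_xy[i, 2],
                            3, 192, 192)
  }, 0))
  expect_equal(detected_px, as.integer(oracle_px))
  expect_equal(as.integer(sort(g$truth$punctum_px_counts)), as.integer(oracle_px))
})

test_that("detection is offset-invariant and monotone in the threshold", {
  g <- gen_fa_image(n_puncta = 8, seed = 3)
  bg <- rect_mask(1, 1, 12, 12, c(192, 192))
  n0 <- length(detect_puncta(g$image, g$cell_mask, bg)$regions)
  shifted <- image_plane(g$image$pixels + 50, g$image$pixel_size, "vinculin")
  expect_equal(length(detect_puncta(shifted, g$cell_mask, bg)$regions), n0)

  counts <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.95), function(r) {
    length(detect_puncta(g$image, g$cell_mask, bg, rel_threshold = r)$regions)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("fa_metrics aggregates areas, fraction and intensities", {
  img <- image_plane({
    px <- matrix(0, 40, 40)
    px[5:7, 5:7] <- 200; px[20:22, 20:22] <- 200
    px
  }, 1, "vinculin")
  cell <- rect_mask(4, 4, 33, 33, c(40, 40))   # 900 px
  bg <- rect_mask(1, 1, 2, 40, c(40, 40))
  ps <- detect_puncta(img, cell, bg, rel_threshold = 0.5, min_area_px = 4)
  m <- fa_metrics(ps)
  expect_equal(m$fa_count, 2)
  expect_equal(m$fa_total_area_um2, 18)
  expect_equal(m$fa_area_fraction, 0.02)
  expect_equal(m$fa_mean_intensity, 200)
  expect_gte(m$fa_area_fraction, 0)
  expect_lte(m$fa_area_fraction, 1)

  empty <- detect_puncta(image_plane(matrix(5, 40, 40), 1), cell, bg)
  expect_equal(unlist(fa_metrics(empty)), c(fa_count = 0, fa_total_area_um2 = 0,
                                            fa_area_fraction = 0,
                                            fa_mean_intensity = 0,
                                            fa_mean_intensity_raw = 0))
})

test_that("metrics match the generator's bookkeeping on planted truth", {
  g <- gen_fa_image(n_puncta = 9, radius_px = 3, seed = 12)
  bg <- rect_mask(1, 1, 12, 12, c(192, 192))
  m <- fa_metrics(detect_puncta(g$image, g$cell_mask, bg))
  expect_equal(m$fa_count, 9)
  expect_equal(m$fa_total_area_um2,
               sum(g$truth$punctum_px_counts) * g$truth$pixel_size^2)
  expect_equal(m$fa_area_fraction,
               m$fa_total_area_um2 / cell_area(g$cell_mask, g$truth$pixel_size))
})

test_that("count_objects counts separated blobs over a whole frame", {
  centers <- cbind(c(10, 40, 70), c(10, 40, 70))
  img <- make_puncta_image(centers)
  bg <- rect_mask(1, 75, 5, 80, c(80, 80))
  expect_equal(count_objects(img, bg), 3L)
  expect_equal(count_objects(image_plane(matrix(3, 80, 80), 1), bg), 0L)

  g <- gen_fa_image(n_puncta = 60, radius_px = 2, min_spacing_px = 7,
                    cell_radius_px = 88, img_px = 200, seed = 8)
  bgg <- rect_mask(1, 1, 8, 8, c(200, 200))
  expect_equal(count_objects(g$image, bgg, min_area_px = 4), 60L)
})
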