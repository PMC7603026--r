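# Focal-adhesion punctum detection and quantification, plus generic object
# counting for stained invasion-filter images.
#
# Detection rule: threshold at background mean + rel_threshold * (in-cell
# maximum - background mean), take connected components (8-connectivity by
# default) within the cell mask, and keep components of at least min_area_px
# pixels. Anchoring the threshold to the background and the in-cell maximum
# makes detection invariant to a constant illumination offset. Touching
# puncta are not split (no watershed) — a declared limitation.

#' Label connected components of a binary matrix
#'
#' Two-pass union-find labeling with 8- (default) or 4-connectivity.
#' Labels are assigned in raster order, 1..n.
#'
#' @param bw logical (or 0/1) matrix.
#' @param connectivity 8 or 4.
#' @return integer matrix of labels (0 = background).
#' @export
label_components <- function(bw, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  bw <- bw != 0
  nr <- nrow(bw); nc <- ncol(bw)
  lab <- matrix(0L, nr, nc)
  fg <- which(bw, arr.ind = TRUE)
  if (nrow(fg) == 0) return(lab)
  fg <- fg[order(fg[, 1], fg[, 2]), , drop = FALSE]
  parent <- integer(0)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offs <- if (connectivity == 4) {
    list(c(-1L, 0L), c(0L, -1L))
  } else {
    list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(-1L, 1L))
  }
  for (k in seq_len(nrow(fg))) {
    r <- fg[k, 1]; c <- fg[k, 2]
    neigh <- integer(0)
    for (o in offs) {
      rr <- r + o[1]; cc <- c + o[2]
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && lab[rr, cc] > 0)
        neigh <- c(neigh, lab[rr, cc])
    }
    if (length(neigh) == 0) {
      parent <- c(parent, length(parent) + 1L)
      lab[r, c] <- length(parent)
    } else {
      roots <- unique(vapply(neigh, find, 1L))
      root <- min(roots)
      lab[r, c] <- root
      for (rt in roots) parent[rt] <- root
    }
  }
  # resolve and renumber 1..n in raster order of first appearance
  roots <- vapply(seq_along(parent), find, 1L)
  idx <- lab[fg]
  final <- roots[idx]
  renum <- match(final, unique(final[order(fg[, 1], fg[, 2])]))
  lab[fg] <- renum
  lab
}

#' Detect focal-adhesion puncta within a cell
#'
#' @param image an [image_plane] (vinculin channel).
#' @param cell_mask [region_mask] of the cell.
#' @param background_region [region_mask] free of signal, disjoint from the
#'   cell.
#' @param rel_threshold relative threshold in (0, 1]: the cut is at
#'   background mean + `rel_threshold` times the background-to-maximum range
#'   within the cell.
#' @param min_area_px minimum component size in pixels (>= 1).
#' @param connectivity 8 (default) or 4.
#' @param clip_negative clip negative background-subtracted intensities to 0.
#' @return object of class `punctum_set`: `regions` (list of [region_mask]),
#'   `area_um2`, `mean_intensity` (background-subtracted, per region),
#'   `mean_intensity_raw`, `cell_area_um2`, `threshold`, and the parameters
#'   used. A flat image (in-cell maximum equal to the background mean)
#'   yields an empty set.
#' @export
detect_puncta <- function(image, cell_mask, background_region,
                          rel_threshold = 0.5, min_area_px = 4,
                          connectivity = 8, clip_negative = TRUE) {
  stopifnot(inherits(image, "image_plane"), inherits(cell_mask, "region_mask"),
            inherits(background_region, "region_mask"))
  if (!(rel_threshold > 0 && rel_threshold <= 1))
    stop("'rel_threshold' must be in (0, 1]")
  if (min_area_px < 1) stop("'min_area_px' must be >= 1")
  if (mask_overlaps(cell_mask, background_region))
    stop("background region overlaps the cell mask")
  px <- image$pixels
  b <- mean(px[background_region$coords])
  mx <- max(px[cell_mask$coords])
  cell_area_um2 <- cell_area(cell_mask, image$pixel_size)
  empty <- function(thr) {
    structure(list(regions = list(), area_um2 = numeric(0),
                   mean_intensity = numeric(0), mean_intensity_raw = numeric(0),
                   cell_area_um2 = cell_area_um2, threshold = thr,
                   params = list(rel_threshold = rel_threshold,
                                 min_area_px = min_area_px,
                                 connectivity = connectivity)),
              class = "punctum_set")
  }
  if (mx <= b) return(empty(NA_real_))
  thr <- b + rel_threshold * (mx - b)
  bw <- matrix(FALSE, nrow(px), ncol(px))
  inside <- px[cell_mask$coords] >= thr
  bw[cell_mask$coords[inside, , drop = FALSE]] <- TRUE
  lab <- label_components(bw, connectivity)
  n <- max(lab)
  if (n == 0) return(empty(thr))
  keep <- which(tabulate(lab[lab > 0], nbins = n) >= min_area_px)
  if (length(keep) == 0) return(empty(thr))
  regions <- lapply(seq_along(keep), function(i) {
    idx <- which(lab == keep[i], arr.ind = TRUE)
    region_mask(idx, dim(px), label = i)
  })
  sub <- function(reg) {
    v <- px[reg$coords] - b
    if (clip_negative) v <- pmax(v, 0)
    mean(v)
  }
  structure(list(
    regions = regions,
    area_um2 = vapply(regions, function(r) mask_size(r) * image$pixel_size^2, 0),
    mean_intensity = vapply(regions, sub, 0),
    mean_intensity_raw = vapply(regions, function(r) mean(px[r$coords]), 0),
    cell_area_um2 = cell_area_um2,
    threshold = thr,
    params = list(rel_threshold = rel_threshold, min_area_px = min_area_px,
                  connectivity = connectivity)
  ), class = "punctum_set")
}

#' @export
print.punctum_set <- function(x, ...) {
  cat(sprintf("<punctum_set> %d puncta, total %.2f um2 in a %.2f um2 cell\n",
              length(x$regions), sum(x$area_um2), x$cell_area_um2))
  invisible(x)
}

#' Per-cell focal-adhesion metrics
#'
#' @param punctum_set a `punctum_set` from [detect_puncta()].
#' @return one-row data.frame: `fa_count`, `fa_total_area_um2`,
#'   `fa_area_fraction` (total punctum area over cell area, in \[0, 1\]),
#'   `fa_mean_intensity` (area-weighted mean of background-subtracted
#'   region intensities) and `fa_mean_intensity_raw`. An empty set gives
#'   zeros.
#' @export
fa_metrics <- function(punctum_set) {
  stopifnot(inherits(punctum_set, "punctum_set"))
  n <- length(punctum_set$regions)
  if (n == 0) {
    return(data.frame(fa_count = 0L, fa_total_area_um2 = 0,
                      fa_area_fraction = 0, fa_mean_intensity = 0,
                      fa_mean_intensity_raw = 0))
  }
  a <- punctum_set$area_um2
  data.frame(
    fa_count = n,
    fa_total_area_um2 = sum(a),
    fa_area_fraction = sum(a) / punctum_set$cell_area_um2,
    fa_mean_intensity = sum(a * punctum_set$mean_intensity) / sum(a),
    fa_mean_intensity_raw = sum(a * punctum_set$mean_intensity_raw) / sum(a)
  )
}

#' Count stained objects in a whole frame
#'
#' Generic object counting for invasion-filter images: same thresholding
#' and size filter as [detect_puncta()] but over the entire frame.
#'
#' @inheritParams detect_puncta
#' @return integer count.
#' @export
count_objects <- function(image, background_region, rel_threshold = 0.5,
                          min_area_px = 4, connectivity = 8) {
  stopifnot(inherits(image, "image_plane"))
  px <- image$pixels
  b <- mean(px[background_region$coords])
  mx <- max(px)
  if (mx <= b) return(0L)
  thr <- b + rel_threshold * (mx - b)
  lab <- label_components(px >= thr, connectivity)
  n <- max(lab)
  if (n == 0) return(0L)
  sum(tabulate(lab[lab > 0], nbins = n) >= min_area_px)
}
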