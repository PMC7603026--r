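# Per-cell geometry and intensity measures for scratch-assay morphometry:
# area, polarity distance, background-subtracted fluorescence, and the
# minimal-bounding-rectangle angle relative to the wound frontline.

#' Cell area in square micrometres
#'
#' @param cell_mask a [region_mask].
#' @param pixel_size micrometres per pixel.
#' @return pixel count times `pixel_size^2`.
#' @export
cell_area <- function(cell_mask, pixel_size) {
  stopifnot(inherits(cell_mask, "region_mask"), pixel_size > 0)
  mask_size(cell_mask) * pixel_size^2
}

#' Nucleus-to-centroid polarity distance
#'
#' Distance between the nucleus-mask centroid and the cell-mask centroid
#' (the geometric centre of mass of the binary mask), in micrometres. Large
#' values indicate a polarized, front-rear organized cell; values near zero
#' a symmetric one.
#'
#' @param cell a [cell_record], or a cell `region_mask` when
#'   `nucleus_mask` is given separately.
#' @param nucleus_mask optional nucleus `region_mask` (when `cell` is a mask).
#' @param pixel_size micrometres per pixel (when `cell` is a mask).
#' @return distance in micrometres.
#' @export
polarity_distance <- function(cell, nucleus_mask = NULL, pixel_size = NULL) {
  if (inherits(cell, "cell_record")) {
    nucleus_mask <- cell$nucleus_mask
    pixel_size <- cell$pixel_size
    cell <- cell$cell_mask
  }
  stopifnot(inherits(cell, "region_mask"), inherits(nucleus_mask, "region_mask"),
            is.numeric(pixel_size), pixel_size > 0)
  d <- mask_centroid(cell) - mask_centroid(nucleus_mask)
  sqrt(sum(d^2)) * pixel_size
}

#' Background-subtracted intensity over a cell mask
#'
#' The background level is the mean intensity over a user-selected region
#' free of signal (no microtubules, no adhesions); it is subtracted
#' per pixel before summing over the cell. Negative per-pixel differences
#' are clipped to zero by default (fluorescence cannot be negative); the raw
#' (unsubtracted) sums are returned alongside.
#'
#' @param cell_mask a [region_mask].
#' @param image an [image_plane] on the same grid.
#' @param background_region a [region_mask] disjoint from `cell_mask`.
#' @param clip_negative clip negative background-subtracted values to 0
#'   (default `TRUE`).
#' @return list with `total_intensity`, `mean_intensity` (background-
#'   subtracted), `total_intensity_raw`, `mean_intensity_raw`, and
#'   `background_level`.
#' @export
intensity_stats <- function(cell_mask, image, background_region,
                            clip_negative = TRUE) {
  stopifnot(inherits(cell_mask, "region_mask"),
            inherits(image, "image_plane"),
            inherits(background_region, "region_mask"))
  if (!identical(as.integer(dim(image$pixels)), cell_mask$dim))
    stop("image and mask grids differ")
  if (mask_overlaps(cell_mask, background_region))
    stop("background region overlaps the cell mask")
  b <- mean(image$pixels[background_region$coords])
  vals <- image$pixels[cell_mask$coords] - b
  if (clip_negative) vals <- pmax(vals, 0)
  raw <- image$pixels[cell_mask$coords]
  list(total_intensity = sum(vals),
       mean_intensity = mean(vals),
       total_intensity_raw = sum(raw),
       mean_intensity_raw = mean(raw),
       background_level = b)
}

#' Minimal-area bounding rectangle
#'
#' Fits the minimum-area enclosing rectangle of the mask's pixel-centre
#' point set by rotating calipers over the convex hull: the optimal
#' rectangle has one side collinear with a hull edge, so each hull edge is
#' examined in turn. Because the rectangle encloses pixel centres, a
#' 10-pixel-wide axis-aligned mask has a long edge of length 9.
#'
#' Ties in minimal area are broken by the smallest long-edge angle to the
#' x-axis (folded to \[0, 90\)). An input whose pixel centres are collinear
#' has no rectangle of positive width and is rejected.
#'
#' @param x a [region_mask], or an n-by-2 matrix of `(x, y)` points.
#' @return object of class `bounding_rect`: `center` (x, y), `long_edge_length`,
#'   `short_edge_length` (pixel units), `long_edge_direction` (unit x, y),
#'   `area`, and `square` (TRUE when the two edges are equal, in which case
#'   orientation is meaningless).
#' @export
min_bounding_rect <- function(x) {
  pts <- if (inherits(x, "region_mask")) {
    cbind(x = x$coords[, 2], y = x$coords[, 1])
  } else {
    stopifnot(is.matrix(x) || is.data.frame(x), ncol(x) == 2)
    cbind(x = as.numeric(x[, 1]), y = as.numeric(x[, 2]))
  }
  if (nrow(pts) < 1) stop("empty point set")
  hull <- grDevices::chull(pts)
  hp <- pts[hull, , drop = FALSE]
  n <- nrow(hp)
  if (n < 3) stop("mask pixel centres are collinear; no bounding rectangle with positive width")
  best <- NULL
  for (i in seq_len(n)) {
    e <- hp[if (i == n) 1 else i + 1, ] - hp[i, ]
    len <- sqrt(sum(e^2))
    if (len == 0) next
    u <- e / len              # edge direction
    v <- c(-u[2], u[1])       # inward normal
    s <- hp %*% u
    t <- hp %*% v
    w <- max(s) - min(s)
    h <- max(t) - min(t)
    area <- w * h
    if (h == 0 || w == 0) next
    long_dir <- if (w >= h) u else v
    cand <- list(
      center = as.numeric((min(s) + w / 2) * u + (min(t) + h / 2) * v),
      long_edge_length = max(w, h),
      short_edge_length = min(w, h),
      long_edge_direction = canonical_direction(long_dir),
      area = area,
      square = isTRUE(all.equal(w, h))
    )
    if (is.null(best) || area < best$area - 1e-12 ||
        (abs(area - best$area) <= 1e-12 &&
         folded_axis_angle(cand$long_edge_direction) <
         folded_axis_angle(best$long_edge_direction))) {
      best <- cand
    }
  }
  if (is.null(best)) stop("mask pixel centres are collinear; no bounding rectangle with positive width")
  names(best$center) <- c("x", "y")
  structure(best, class = "bounding_rect")
}

# orientations are axial (direction and its negation are the same axis);
# report the representative with angle in [0, 180) from the +x axis
canonical_direction <- function(v) {
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  names(v) <- c("x", "y")
  v
}

# angle of an axial direction to the x-axis, folded to [0, 90]
folded_axis_angle <- function(v) {
  a <- atan2(v[2], v[1]) * 180 / pi
  a <- a %% 180
  if (a > 90) a <- 180 - a
  a
}

#' @export
print.bounding_rect <- function(x, ...) {
  cat(sprintf(
    "<bounding_rect> %.3f x %.3f px at (%.2f, %.2f), long edge dir (%.3f, %.3f)\n",
    x$long_edge_length, x$short_edge_length, x$center[1], x$center[2],
    x$long_edge_direction[1], x$long_edge_direction[2]))
  invisible(x)
}

#' Cell angle relative to the wound frontline
#'
#' The frontline (the wound-edge line, perpendicular to the direction of
#' travel into the gap) defines 0 degrees and its perpendicular 90 degrees;
#' the unsigned angle between the cell's long edge and the frontline axis is
#' folded into \[0, 90\]: angles above 90 reflect as `180 - angle`.
#'
#' @param rect a `bounding_rect` from [min_bounding_rect()].
#' @param frontline_direction `c(x, y)` direction of travel, pointing from
#'   the monolayer into the cell-free gap; the frontline axis is its
#'   perpendicular.
#' @param complement return `90 - angle` instead, for plots that call the
#'   leading edge 90 degrees (default `FALSE`).
#' @return angle in degrees within \[0, 90\].
#' @export
frontline_angle <- function(rect, frontline_direction, complement = FALSE) {
  stopifnot(inherits(rect, "bounding_rect"))
  if (isTRUE(rect$square)) {
    warning("bounding rectangle is square; orientation undefined, reporting 0 degrees")
    return(if (complement) 90 else 0)
  }
  fd <- unit_vector(frontline_direction)
  axis <- perp_vector(fd)
  u <- rect$long_edge_direction
  theta <- unname((atan2(u[2], u[1]) - atan2(axis[2], axis[1])) * 180 / pi)
  theta <- theta %% 180
  if (theta > 90) theta <- 180 - theta
  if (complement) 90 - theta else theta
}

#' All morphometry measures for one cell
#'
#' Computes the five per-cell measures of the scratch-assay analysis: area,
#' polarity distance, total and mean background-subtracted intensity of the
#' named channel, and the minimal-bounding-rectangle angle to the frontline.
#'
#' @param record a [cell_record].
#' @param background_region a [region_mask] of a signal-free area.
#' @param channel name of the channel to quantify (default `"tubulin"`).
#' @param clip_negative see [intensity_stats()].
#' @return one-row data.frame: `area_um2`, `polarity_um`, `total_intensity`,
#'   `mean_intensity`, `total_intensity_raw`, `mean_intensity_raw`,
#'   `angle_deg`.
#' @export
measure_cell <- function(record, background_region, channel = "tubulin",
                         clip_negative = TRUE) {
  stopifnot(inherits(record, "cell_record"))
  if (!channel %in% names(record$channels))
    stop("cell record has no channel '", channel, "'")
  img <- record$channels[[channel]]
  stats <- intensity_stats(record$cell_mask, img, background_region,
                           clip_negative = clip_negative)
  rect <- min_bounding_rect(record$cell_mask)
  data.frame(
    area_um2 = cell_area(record$cell_mask, record$pixel_size),
    polarity_um = polarity_distance(record),
    total_intensity = stats$total_intensity,
    mean_intensity = stats$mean_intensity,
    total_intensity_raw = stats$total_intensity_raw,
    mean_intensity_raw = stats$mean_intensity_raw,
    angle_deg = frontline_angle(rect, record$frontline_direction)
  )
}
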