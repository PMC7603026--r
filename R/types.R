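#' Construct an image plane
#'
#' A single 2D fluorescence or phase-contrast channel with its physical
#' calibration. Pixel values are stored as given (no rescaling); the grid is a
#' numeric matrix indexed `[row, col]` with origin at the top-left, so
#' `x = column`, `y = row` (1-based, R convention). All physical outputs use
#' micrometres via `pixel_size`.
#'
#' @param pixels numeric matrix of non-negative, finite intensities.
#' @param pixel_size micrometres per pixel (isotropic), > 0.
#' @param channel_label free-text channel name, e.g. `"tubulin"`,
#'   `"vinculin"`, `"dapi"`.
#' @return an object of class `image_plane`.
#' @export
image_plane <- function(pixels, pixel_size, channel_label = "") {
  pixels <- as.matrix(pixels)
  if (!is.numeric(pixels) || nrow(pixels) < 1 || ncol(pixels) < 1)
    stop("'pixels' must be a non-empty numeric matrix")
  if (any(!is.finite(pixels)))
    stop("image intensities must be finite")
  if (any(pixels < 0))
    stop("image intensities must be non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("'pixel_size' must be a single positive number (micrometres/pixel)")
  structure(
    list(pixels = pixels, pixel_size = pixel_size,
         channel_label = as.character(channel_label)),
    class = "image_plane"
  )
}

#' @export
print.image_plane <- function(x, ...) {
  cat(sprintf("<image_plane> %d x %d px, %.4g um/px, channel '%s'\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$channel_label))
  invisible(x)
}

#' Construct a region mask
#'
#' A set of pixels (a segmented cell, nucleus, punctum, or spheroid outline)
#' on a known image grid. Coordinates are 1-based `(row, col)` pixel indices;
#' geometric computations treat pixel `(r, c)` as the point `(x = c, y = r)`
#' (its centre), so a 10-pixel-wide mask has a point-set extent of 9.
#'
#' @param coords two-column integer matrix of `(row, col)` pixel coordinates.
#' @param dim integer vector `c(nrow, ncol)` of the underlying image grid.
#' @param label integer region id (> 0).
#' @return an object of class `region_mask`.
#' @export
region_mask <- function(coords, dim, label = 1L) {
  coords <- matrix(as.integer(round(coords)), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  if (nrow(coords) == 0) stop("region mask must be non-empty")
  dim <- as.integer(dim)
  if (length(dim) != 2 || any(dim < 1)) stop("'dim' must be c(nrow, ncol)")
  if (any(coords[, 1] < 1) || any(coords[, 1] > dim[1]) ||
      any(coords[, 2] < 1) || any(coords[, 2] > dim[2]))
    stop("mask coordinates fall outside the image grid")
  if (anyDuplicated(mask_key(coords, dim)))
    stop("mask coordinates contain duplicates")
  structure(list(coords = coords, dim = dim, label = as.integer(label)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> label %d, %d px on %d x %d grid\n",
              x$label, nrow(x$coords), x$dim[1], x$dim[2]))
  invisible(x)
}

# linear index used for set operations between masks on the same grid
mask_key <- function(coords, dim) {
  (coords[, 2] - 1L) * dim[1] + coords[, 1]
}

#' Convert a region mask to a logical matrix
#' @param mask a `region_mask`.
#' @return logical matrix of the mask's grid dimensions.
#' @export
mask_to_matrix <- function(mask) {
  m <- matrix(FALSE, mask$dim[1], mask$dim[2])
  m[mask$coords] <- TRUE
  m
}

#' Build a region mask from a logical matrix
#' @param m logical (or 0/1 numeric) matrix.
#' @param label integer region id.
#' @return a `region_mask`.
#' @export
matrix_to_mask <- function(m, label = 1L) {
  idx <- which(m != 0, arr.ind = TRUE)
  region_mask(idx, dim(m), label)
}

#' Number of pixels in a mask
#' @param mask a `region_mask`.
#' @return integer pixel count.
#' @export
mask_size <- function(mask) nrow(mask$coords)

#' Test whether one mask is a subset of another (same grid)
#' @param inner,outer `region_mask` objects on the same grid.
#' @return logical.
#' @export
mask_is_subset <- function(inner, outer) {
  if (!identical(inner$dim, outer$dim))
    stop("masks are defined on different grids")
  all(mask_key(inner$coords, inner$dim) %in% mask_key(outer$coords, outer$dim))
}

#' Test whether two masks overlap (same grid)
#' @param a,b `region_mask` objects on the same grid.
#' @return logical.
#' @export
mask_overlaps <- function(a, b) {
  if (!identical(a$dim, b$dim)) stop("masks are defined on different grids")
  any(mask_key(a$coords, a$dim) %in% mask_key(b$coords, b$dim))
}

#' Centroid of a mask
#'
#' Geometric centroid of the pixel centres, in pixel units `(x = col, y = row)`.
#'
#' @param mask a `region_mask`.
#' @return numeric `c(x, y)` in pixels.
#' @export
mask_centroid <- function(mask) {
  c(x = mean(mask$coords[, 2]), y = mean(mask$coords[, 1]))
}

#' Construct a segmented-cell record
#'
#' Bundles one manually segmented cell at the wound edge: its cell and
#' nucleus masks, named fluorescence channels, the frontline direction, and
#' optionally the MTOC position.
#'
#' @param cell_mask `region_mask` of the whole cell.
#' @param nucleus_mask `region_mask` of the nucleus (must be contained in
#'   `cell_mask`).
#' @param channels named list of `image_plane` objects on the same grid.
#' @param frontline_direction numeric `c(x, y)`; points from the monolayer
#'   into the cell-free gap. Normalised to unit length.
#' @param mtoc_point optional numeric `c(x, y)` MTOC position in micrometres.
#' @param pixel_size micrometres per pixel; defaults to the first channel's.
#' @return an object of class `cell_record`.
#' @export
cell_record <- function(cell_mask, nucleus_mask, channels = list(),
                        frontline_direction = c(1, 0), mtoc_point = NULL,
                        pixel_size = NULL) {
  stopifnot(inherits(cell_mask, "region_mask"),
            inherits(nucleus_mask, "region_mask"))
  if (!mask_is_subset(nucleus_mask, cell_mask))
    stop("nucleus mask is not contained in the cell mask")
  if (length(channels) && is.null(names(channels)))
    stop("'channels' must be a named list of image_plane objects")
  for (ch in channels) {
    stopifnot(inherits(ch, "image_plane"))
    if (!identical(as.integer(dim(ch$pixels)), cell_mask$dim))
      stop("channel image grid does not match the mask grid")
  }
  if (is.null(pixel_size)) {
    if (length(channels)) pixel_size <- channels[[1]]$pixel_size
    else stop("'pixel_size' required when no channels are supplied")
  }
  fd <- unit_vector(frontline_direction)
  structure(list(cell_mask = cell_mask, nucleus_mask = nucleus_mask,
                 channels = channels, frontline_direction = fd,
                 mtoc_point = mtoc_point, pixel_size = pixel_size),
            class = "cell_record")
}

unit_vector <- function(v) {
  v <- as.numeric(v)
  if (length(v) != 2 || !all(is.finite(v))) stop("direction must be a finite 2-vector")
  n <- sqrt(sum(v^2))
  if (n == 0) stop("direction must be non-zero")
  v / n
}

# perpendicular of (x, y): rotate by +90 degrees
perp_vector <- function(v) c(-v[2], v[1])
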