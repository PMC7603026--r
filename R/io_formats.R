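# Image, mask and track I/O.
#
# Conventions (used by every reader/writer in the package):
#   * image grids are matrices indexed [row, col], origin top-left;
#     x = column, y = row, 1-based;
#   * integer intensities are preserved exactly for 8/16-bit TIFF and
#     8/16-bit PNG input; TIFF is the output format for 16-bit data;
#   * physical calibration (micrometres/pixel, minutes/frame) is supplied by
#     the caller and carried on the returned objects.

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit grayscale TIFF or PNG and returns the integer
#' intensities exactly as stored (no rescaling to \[0, 1\]).
#'
#' @param path path to a TIFF or PNG file.
#' @param pixel_size micrometres per pixel (> 0); the calibration is a
#'   required user input and is attached to the result.
#' @param channel_label free-text channel name stored on the result.
#' @param channel for multi-channel files, the 1-based channel index to
#'   extract; an error is raised for multi-channel input without it.
#' @return an [image_plane].
#' @export
read_image <- function(path, pixel_size, channel_label = "", channel = NULL) {
  px <- read_pixels(path, channel)
  image_plane(px, pixel_size = pixel_size, channel_label = channel_label)
}

read_pixels <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, as.is = TRUE)
  } else if (ext == "png") {
    px <- png::readPNG(path) * png_max_value(path)
    px <- round(px)
  } else {
    stop("unsupported image format '", ext, "' (use TIFF or PNG)")
  }
  if (length(dim(px)) == 3) {
    if (is.null(channel))
      stop("multi-channel image: supply 'channel' to select one plane")
    if (channel < 1 || channel > dim(px)[3]) stop("channel index out of range")
    px <- px[, , channel]
  }
  storage.mode(px) <- "double"
  px
}

# PNG stores the bit depth as the 9th byte of the IHDR chunk data
# (file offset 25, 1-based); readPNG rescales to [0, 1] by 2^depth - 1.
png_max_value <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = 25)
  depth <- as.integer(hdr[25])
  if (!depth %in% c(1L, 2L, 4L, 8L, 16L))
    stop("unsupported PNG bit depth: ", depth)
  2^depth - 1
}

#' Write a grayscale image
#'
#' Writes integer intensities losslessly: 8- or 16-bit TIFF, or 8-bit PNG.
#' Grid convention: matrix `[row, col]`, origin top-left, x = column, y = row.
#'
#' @param image an [image_plane] or numeric matrix of integers.
#' @param path output path ending in `.tif`/`.tiff` or `.png`.
#' @param bits 8 or 16; default picks 8 when all values fit, else 16.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = NULL) {
  px <- if (inherits(image, "image_plane")) image$pixels else as.matrix(image)
  if (any(px < 0) || any(px != round(px)))
    stop("write_image() stores integer intensities; got non-integer values")
  if (is.null(bits)) bits <- if (max(px) <= 255) 8L else 16L
  if (!bits %in% c(8L, 16L)) stop("'bits' must be 8 or 16")
  if (max(px) > 2^bits - 1) stop("intensities exceed ", bits, "-bit range")
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(px / (2^bits - 1), path, bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    if (bits != 8) stop("PNG output is 8-bit; use TIFF for 16-bit data")
    png::writePNG(px / 255, path)
  } else {
    stop("unsupported image format '", ext, "' (use TIFF or PNG)")
  }
  invisible(path)
}

#' Read segmented regions from a labeled image
#'
#' Reads a label image (0 = background, k > 0 = pixels of object k) and
#' returns one [region_mask] per non-zero label, labels preserved.
#'
#' @param path path to an 8/16-bit TIFF or PNG label image.
#' @return list of [region_mask] objects, ordered by label.
#' @export
read_masks <- function(path) {
  lab <- read_pixels(path)
  labels_to_masks(lab)
}

labels_to_masks <- function(lab) {
  labels <- sort(unique(lab[lab > 0]))
  if (length(labels) == 0) stop("no regions: label image is all zero")
  lapply(labels, function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    region_mask(idx, dim(lab), label = as.integer(k))
  })
}

#' Write region masks as a labeled image
#'
#' Inverse of [read_masks()]: regions are painted with their labels on a
#' zero background and written as a 16-bit TIFF (or 8-bit PNG when all
#' labels are below 256). Regions must be disjoint. Grid convention:
#' `[row, col]`, origin top-left, x = column, y = row, 1-based.
#'
#' @param masks list of [region_mask] objects on a common grid.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_masks <- function(masks, path) {
  stopifnot(length(masks) >= 1)
  d <- masks[[1]]$dim
  lab <- matrix(0, d[1], d[2])
  for (m in masks) {
    if (!identical(m$dim, d)) stop("masks are defined on different grids")
    if (any(lab[m$coords] != 0)) stop("masks overlap; labels would collide")
    lab[m$coords] <- m$label
  }
  ext <- tolower(tools::file_ext(path))
  bits <- if (ext == "png") 8L else 16L
  write_image(lab, path, bits = bits)
}

#' Read single-cell migration tracks
#'
#' Reads a tracking-table CSV in the minimal manual-tracking dialect: a
#' header row and columns for cell id, frame index, x and y pixel position
#' (extra columns are ignored). Column names are matched case-insensitively
#' against common aliases (`cell_id`/`track`/`track_no`/`id`/`cell`;
#' `frame`/`frame_index`/`slice`/`t`; `x`/`x_px`; `y`/`y_px`). The frame
#' interval has no column in this dialect and is supplied out-of-band.
#'
#' @param path CSV path.
#' @param frame_interval minutes between consecutive frames (> 0).
#' @return a `track_table`: data.frame with columns `cell_id`, `frame`,
#'   `x`, `y` (pixels; x = column, y = row, 1-based origin top-left), sorted
#'   by (cell_id, frame), with attribute `frame_interval` in minutes.
#' @export
read_tracks <- function(path, frame_interval) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  pick <- function(aliases, what) {
    hit <- which(tolower(names(df)) %in% aliases)
    if (length(hit) == 0) stop("track CSV lacks a ", what, " column")
    hit[1]
  }
  out <- data.frame(
    cell_id = df[[pick(c("cell_id", "track", "track_no", "id", "cell"), "cell id")]],
    frame   = as.integer(df[[pick(c("frame", "frame_index", "slice", "t"), "frame")]]),
    x       = as.numeric(df[[pick(c("x", "x_px"), "x")]]),
    y       = as.numeric(df[[pick(c("y", "y_px"), "y")]])
  )
  track_table(out, frame_interval)
}

#' Construct and validate a track table
#'
#' @param df data.frame with columns `cell_id`, `frame`, `x`, `y`.
#' @param frame_interval minutes between frames (> 0).
#' @return validated `track_table`, sorted by (cell_id, frame).
#' @export
track_table <- function(df, frame_interval) {
  stopifnot(all(c("cell_id", "frame", "x", "y") %in% names(df)))
  if (!is.numeric(frame_interval) || length(frame_interval) != 1 ||
      frame_interval <= 0)
    stop("'frame_interval' must be a single positive number of minutes")
  if (any(!is.finite(df$x)) || any(!is.finite(df$y)))
    stop("track coordinates must be finite")
  for (id in unique(df$cell_id)) {
    fr <- df$frame[df$cell_id == id]
    if (length(fr) < 2)
      stop("track '", id, "' has fewer than 2 points")
    if (anyDuplicated(fr))
      stop("duplicate (cell_id, frame) pair in track '", id, "'")
    if (any(diff(fr) <= 0))
      stop("frames are not strictly increasing in track '", id, "'")
  }
  df <- df[order(df$cell_id, df$frame), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, frame_interval = frame_interval,
            class = c("track_table", "data.frame"))
}

#' Write a track table as CSV
#'
#' Writes columns `cell_id`, `frame`, `x`, `y` (pixel units; x = column,
#' y = row, origin top-left, 1-based). The frame interval is not stored in
#' the file (the dialect has no time column); keep it with the metadata.
#'
#' @param tracks a `track_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path) {
  df <- as.data.frame(tracks)[, c("cell_id", "frame", "x", "y")]
  # %.17g round-trips doubles exactly through the CSV
  df$x <- sprintf("%.17g", df$x)
  df$y <- sprintf("%.17g", df$y)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
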