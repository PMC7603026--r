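# Single-cell migration statistics: accumulated distance, Euclidean
# (start-to-end) distance, directionality (directness ratio), and velocity,
# plus the wound-edge migration rate.

#' Migration statistics of one track
#'
#' * accumulated distance: sum of consecutive step lengths (micrometres);
#' * Euclidean distance: straight-line start-to-end distance;
#' * directionality (directness): Euclidean / accumulated, 1 for a
#'   perfectly straight path, reported as `NA` for a stationary track;
#' * velocity: accumulated distance over elapsed time (micrometres/hour),
#'   the usual chemotaxis-tool convention; the straight-line variant is
#'   reported separately as `straight_speed_um_per_h` to avoid ambiguity.
#'
#' Elapsed time is `(n_frames - 1) * frame_interval`.
#'
#' @param track data.frame with columns `x`, `y` (pixels) for a single cell,
#'   ordered by frame.
#' @param pixel_size micrometres per pixel.
#' @param frame_interval minutes between consecutive frames; defaults to the
#'   `track_table` attribute when present, else 12 minutes (the standard
#'   time-lapse interval for these assays).
#' @return one-row data.frame: `n_frames`, `accumulated_um`, `euclidean_um`,
#'   `directionality`, `velocity_um_per_h`, `straight_speed_um_per_h`.
#' @export
track_stats <- function(track, pixel_size = 1,
                        frame_interval = attr(track, "frame_interval") %||% 12) {
  stopifnot(all(c("x", "y") %in% names(track)))
  n <- nrow(track)
  if (n < 2) stop("a track needs at least 2 points")
  dx <- diff(track$x) * pixel_size
  dy <- diff(track$y) * pixel_size
  steps <- sqrt(dx^2 + dy^2)
  accumulated <- sum(steps)
  euclidean <- sqrt((sum(dx))^2 + (sum(dy))^2)
  elapsed_h <- (n - 1) * frame_interval / 60
  data.frame(
    n_frames = n,
    accumulated_um = accumulated,
    euclidean_um = euclidean,
    directionality = if (accumulated > 0) euclidean / accumulated else NA_real_,
    velocity_um_per_h = accumulated / elapsed_h,
    straight_speed_um_per_h = euclidean / elapsed_h
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Migration statistics for every cell in a track table
#'
#' @param tracks a `track_table` (see [read_tracks()]).
#' @param pixel_size micrometres per pixel.
#' @return data.frame with one row per `cell_id`.
#' @export
track_stats_all <- function(tracks, pixel_size = 1) {
  fi <- attr(tracks, "frame_interval")
  ids <- unique(tracks$cell_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    tr <- tracks[tracks$cell_id == id, , drop = FALSE]
    cbind(cell_id = id, track_stats(tr, pixel_size, fi))
  }))
  rownames(out) <- NULL
  out
}

#' Population summary of per-cell statistics
#'
#' Mean, SD, SEM and n per metric. The SD (and SEM) of a single observation
#' is reported as `NA`, not 0.
#'
#' @param stats data.frame of per-cell statistics (numeric columns are
#'   summarised), or a numeric vector.
#' @return data.frame with columns `metric`, `mean`, `sd`, `sem`, `n`.
#' @export
population_summary <- function(stats) {
  if (is.numeric(stats)) stats <- data.frame(value = stats)
  num <- stats[vapply(stats, is.numeric, TRUE)]
  if (ncol(num) == 0 || nrow(num) == 0) stop("no numeric values to summarise")
  rows <- lapply(names(num), function(nm) {
    v <- num[[nm]][!is.na(num[[nm]])]
    n <- length(v)
    s <- if (n >= 2) stats::sd(v) else NA_real_
    data.frame(metric = nm, mean = if (n) mean(v) else NA_real_,
               sd = s, sem = s / sqrt(n), n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wound-edge migration rate
#'
#' Ordinary least-squares slope of the monolayer edge advance (micrometres,
#' measured from the initial edge position toward the gap mid-centre)
#' against time (hours).
#'
#' @param time_h numeric vector of times in hours (>= 2 distinct values).
#' @param advance_um edge advance at each time, micrometres.
#' @return list with `velocity_um_per_h` (slope), `intercept_um`, and
#'   `stderr` (standard error of the slope; `NA` with 2 points).
#' @export
edge_velocity <- function(time_h, advance_um) {
  stopifnot(length(time_h) == length(advance_um), length(time_h) >= 2)
  if (length(unique(time_h)) < 2) stop("all time points are equal")
  fit <- stats::lm(advance_um ~ time_h)
  # a perfect line is a legitimate input (summary.lm warns about it)
  co <- suppressWarnings(summary(fit)$coefficients)
  list(velocity_um_per_h = unname(co["time_h", "Estimate"]),
       intercept_um = unname(co["(Intercept)", "Estimate"]),
       stderr = unname(co["time_h", "Std. Error"]))
}
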