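# Seeded synthetic-data generators with ground truth.
#
# Every generator returns the artifact plus a `truth` list that fully
# determines it given the seed, so each pipeline stage has a recovery test
# that reads only generator outputs. Determinism contract: identical
# (parameters, seed) give bit-identical results.
#
# Rasterization rule used throughout: a pixel belongs to a disk/ellipse iff
# its centre lies inside the continuous shape ("center-in" rule).

#' Generate a synthetic stained cell at the wound edge
#'
#' An elliptical cell whose major axis makes `orientation_deg` with the
#' frontline axis (the wound-edge line; 0 means elongated along the wound
#' edge, 90 elongated into the gap), with a circular nucleus displaced by
#' `nucleus_offset_um` along the rear axis (away from the gap), and a
#' tubulin-like channel equal to `background_level` plus
#' `tubulin_amplitude` inside the cell plus Gaussian noise, quantized to
#' 16-bit integers.
#'
#' @param orientation_deg major-axis angle to the frontline axis, degrees.
#' @param axis_ratio major/minor semi-axis ratio (>= 1).
#' @param nucleus_offset_um nucleus displacement towards the cell rear, µm.
#' @param semi_minor_um minor semi-axis, µm.
#' @param nucleus_radius_um nucleus radius, µm.
#' @param tubulin_amplitude mean in-cell signal above background (counts).
#' @param background_level mean background (counts).
#' @param noise_sd Gaussian pixel noise SD (counts); the generated SNR is
#'   `tubulin_amplitude / noise_sd`.
#' @param pixel_size micrometres per pixel; the default 0.1 emulates a
#'   63x oil objective at Nyquist-level zoom on a laser-scanning confocal.
#' @param img_px square image side, pixels; `NULL` (default) sizes the grid
#'   to fit the rotated cell. Minimal-bounding-rectangle orientation
#'   readout is a discrete estimator: it needs the major axis to span a few
#'   hundred pixels (as with the defaults) to resolve angles to ~2 degrees.
#' @param frontline_direction `c(x, y)` towards the gap.
#' @param poisson_noise add Poisson shot noise instead of Gaussian
#'   (variance equal to the noise-free signal), `noise_sd` then ignored.
#' @param seed RNG seed (applied locally; the global RNG state is restored).
#' @return list: `image` ([image_plane], channel `"tubulin"`), `cell_mask`,
#'   `nucleus_mask`, `record` (assembled [cell_record]), `truth`.
#' @export
gen_cell_image <- function(orientation_deg = 30, axis_ratio = 2,
                           nucleus_offset_um = 4, semi_minor_um = 20,
                           nucleus_radius_um = 6, tubulin_amplitude = 120,
                           background_level = 100, noise_sd = 6,
                           pixel_size = 0.1, img_px = NULL,
                           frontline_direction = c(1, 0),
                           poisson_noise = FALSE, seed = 1) {
  if (is.null(img_px))
    img_px <- 2 * ceiling(axis_ratio * semi_minor_um / pixel_size) + 31
  stopifnot(axis_ratio >= 1, tubulin_amplitude >= 0, background_level >= 0,
            noise_sd >= 0, pixel_size > 0, img_px >= 16)
  fd <- unit_vector(frontline_direction)
  axis <- perp_vector(fd)
  th <- orientation_deg * pi / 180
  major_dir <- cos(th) * axis + sin(th) * fd
  minor_dir <- perp_vector(major_dir)
  a_px <- axis_ratio * semi_minor_um / pixel_size
  b_px <- semi_minor_um / pixel_size
  ctr <- c((img_px + 1) / 2, (img_px + 1) / 2)  # (x, y)
  cc <- expand.grid(row = seq_len(img_px), col = seq_len(img_px))
  relx <- cc$col - ctr[1]
  rely <- cc$row - ctr[2]
  u <- (relx * major_dir[1] + rely * major_dir[2]) / a_px
  v <- (relx * minor_dir[1] + rely * minor_dir[2]) / b_px
  inside <- u^2 + v^2 <= 1
  if (!any(inside)) stop("cell ellipse does not intersect the image grid")
  cell <- region_mask(cbind(cc$row[inside], cc$col[inside]),
                      c(img_px, img_px), 1L)
  nctr <- ctr - (nucleus_offset_um / pixel_size) * fd
  r_px <- nucleus_radius_um / pixel_size
  nin <- (cc$col - nctr[1])^2 + (cc$row - nctr[2])^2 <= r_px^2
  if (!any(nin)) stop("nucleus does not cover any pixel")
  if (any(nin & !inside)) stop("nucleus would fall outside the cell")
  nucleus <- region_mask(cbind(cc$row[nin], cc$col[nin]), c(img_px, img_px), 1L)
  signal <- matrix(background_level, img_px, img_px)
  signal[cell$coords] <- background_level + tubulin_amplitude
  px <- withr::with_seed(seed, {
    if (poisson_noise) matrix(stats::rpois(img_px^2, signal), img_px, img_px)
    else signal + matrix(stats::rnorm(img_px^2, 0, noise_sd), img_px, img_px)
  })
  px <- pmin(pmax(round(px), 0), 65535)
  img <- image_plane(px, pixel_size, "tubulin")
  truth <- list(orientation_deg = orientation_deg, axis_ratio = axis_ratio,
                nucleus_offset_um = nucleus_offset_um,
                semi_minor_um = semi_minor_um,
                nucleus_radius_um = nucleus_radius_um,
                tubulin_amplitude = tubulin_amplitude,
                background_level = background_level, noise_sd = noise_sd,
                pixel_size = pixel_size, img_px = img_px,
                frontline_direction = fd, center_px = ctr,
                nucleus_center_px = nctr, seed = seed)
  list(image = img, cell_mask = cell, nucleus_mask = nucleus,
       record = cell_record(cell, nucleus, list(tubulin = img), fd),
       truth = truth)
}

#' Generate a synthetic focal-adhesion (vinculin-like) image
#'
#' Plants `n_puncta` disjoint bright disks inside a circular cell mask by
#' rejection sampling: integer centres at least `min_spacing_px` apart and
#' at least `radius_px + 2` pixels inside the cell boundary. Pixel values
#' are background plus `amplitude` on the disks plus Gaussian noise,
#' quantized to 16-bit.
#'
#' @param n_puncta number of puncta (>= 0).
#' @param radius_px punctum disk radius, pixels.
#' @param min_spacing_px minimum pairwise centre distance, pixels.
#' @param amplitude punctum signal above background (counts).
#' @param background_level mean background (counts).
#' @param noise_sd Gaussian noise SD (counts).
#' @param cell_radius_px radius of the circular cell mask, pixels.
#' @param img_px square image side, pixels.
#' @param pixel_size micrometres per pixel.
#' @param max_attempts rejection-sampling budget before declaring the
#'   packing infeasible.
#' @param seed RNG seed.
#' @return list: `image` ([image_plane], channel `"vinculin"`), `cell_mask`,
#'   `truth` (punctum centres, per-punctum pixel counts, parameters).
#' @export
gen_fa_image <- function(n_puncta = 12, radius_px = 3, min_spacing_px = 10,
                         amplitude = 200, background_level = 100, noise_sd = 8,
                         cell_radius_px = 70, img_px = 192, pixel_size = 0.5,
                         max_attempts = 10000, seed = 1) {
  stopifnot(n_puncta >= 0, radius_px >= 1, min_spacing_px > 0,
            amplitude >= 0, noise_sd >= 0, cell_radius_px > radius_px + 2)
  ctr <- c((img_px + 1) / 2, (img_px + 1) / 2)
  cc <- expand.grid(row = seq_len(img_px), col = seq_len(img_px))
  incell <- (cc$col - ctr[1])^2 + (cc$row - ctr[2])^2 <= cell_radius_px^2
  cell <- region_mask(cbind(cc$row[incell], cc$col[incell]),
                      c(img_px, img_px), 1L)
  res <- withr::with_seed(seed, {
    centers <- matrix(numeric(0), 0, 2)  # (x, y), integer
    rmax <- cell_radius_px - radius_px - 2
    attempts <- 0
    while (nrow(centers) < n_puncta) {
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("punctum packing infeasible within ", max_attempts, " attempts")
      cand <- round(ctr + stats::runif(2, -rmax, rmax))
      if (sum((cand - ctr)^2) > rmax^2) next
      if (nrow(centers) > 0 &&
          min(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2)) <
          min_spacing_px) next
      centers <- rbind(centers, cand)
    }
    signal <- matrix(background_level, img_px, img_px)
    counts <- integer(n_puncta)
    if (n_puncta > 0) for (i in seq_len(n_puncta)) {
      din <- (cc$col - centers[i, 1])^2 + (cc$row - centers[i, 2])^2 <= radius_px^2
      signal[cbind(cc$row[din], cc$col[din])] <- background_level + amplitude
      counts[i] <- sum(din)
    }
    px <- signal + matrix(stats::rnorm(img_px^2, 0, noise_sd), img_px, img_px)
    list(px = pmin(pmax(round(px), 0), 65535), centers = centers,
         counts = counts)
  })
  img <- image_plane(res$px, pixel_size, "vinculin")
  truth <- list(n_puncta = n_puncta, radius_px = radius_px,
                min_spacing_px = min_spacing_px, amplitude = amplitude,
                background_level = background_level, noise_sd = noise_sd,
                cell_radius_px = cell_radius_px, img_px = img_px,
                pixel_size = pixel_size, centers_xy = res$centers,
                punctum_px_counts = res$counts, seed = seed)
  list(image = img, cell_mask = cell, truth = truth)
}

#' Generate persistent / biased random-walk migration tracks
#'
#' Each cell takes `n_steps` steps of constant length `step_um`. The new
#' heading is the previous heading rotated by a Gaussian turn angle with
#' standard deviation `sqrt(-2 * log(persistence))`, then pulled towards
#' `bias_direction` with weight `bias_strength` and renormalised. The turn
#' SD is parameterised so that, without bias, the lag-1 autocorrelation of
#' the step direction `E[cos(turn)]` equals `persistence` exactly:
#' `persistence = 0` is an uncorrelated random walk (uniform new heading)
#' and `persistence -> 1` a straight path. Positions are emitted once per
#' frame. As a demonstration feature (not a mechanistic claim),
#' `bias_switch_every` rotates the bias direction by 90 degrees every so
#' many frames, mimicking an alternating field schedule.
#'
#' @param n_cells number of tracks.
#' @param n_steps steps per track (track has `n_steps + 1` points).
#' @param step_um step length, µm.
#' @param persistence heading persistence in \[0, 1).
#' @param bias_direction `c(x, y)` drift direction (normalised internally).
#' @param bias_strength drift weight (>= 0).
#' @param frame_interval minutes per frame.
#' @param pixel_size micrometres per pixel for the emitted pixel coordinates.
#' @param bias_switch_every optional integer: rotate the bias by 90 degrees
#'   every this many frames (demonstration feature).
#' @param seed RNG seed.
#' @return list: `tracks` (a `track_table`, coordinates in pixels), `truth`.
#' @export
gen_tracks <- function(n_cells = 20, n_steps = 50, step_um = 2,
                       persistence = 0.5, bias_direction = c(1, 0),
                       bias_strength = 0, frame_interval = 12,
                       pixel_size = 1, bias_switch_every = NULL, seed = 1) {
  if (!(persistence >= 0 && persistence < 1))
    stop("'persistence' must be in [0, 1)")
  stopifnot(bias_strength >= 0, n_cells >= 1, n_steps >= 1)
  bd <- unit_vector(bias_direction)
  turn_sd <- if (persistence > 0) sqrt(-2 * log(persistence)) else Inf
  rows <- withr::with_seed(seed, {
    out <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      pos <- matrix(0, n_steps + 1, 2)
      theta <- stats::runif(1, 0, 2 * pi)
      b <- bd
      for (s in seq_len(n_steps)) {
        if (!is.null(bias_switch_every) && s > 1 &&
            (s - 1) %% bias_switch_every == 0) b <- perp_vector(b)
        theta <- if (is.finite(turn_sd)) theta + stats::rnorm(1, 0, turn_sd)
                 else stats::runif(1, 0, 2 * pi)
        v <- c(cos(theta), sin(theta)) + bias_strength * b
        nv <- sqrt(sum(v^2))
        if (nv < 1e-12) v <- c(cos(theta), sin(theta)) else v <- v / nv
        theta <- atan2(v[2], v[1])
        pos[s + 1, ] <- pos[s, ] + step_um * v
      }
      out[[i]] <- data.frame(cell_id = i, frame = seq_len(n_steps + 1) - 1L,
                             x = pos[, 1] / pixel_size,
                             y = pos[, 2] / pixel_size)
    }
    do.call(rbind, out)
  })
  truth <- list(n_cells = n_cells, n_steps = n_steps, step_um = step_um,
                persistence = persistence, bias_direction = bd,
                bias_strength = bias_strength, frame_interval = frame_interval,
                pixel_size = pixel_size, bias_switch_every = bias_switch_every,
                seed = seed)
  list(tracks = track_table(rows, frame_interval), truth = truth)
}

#' Generate concentric spheroid core and dispersal masks
#'
#' Concentric digital disks (center-in rasterization); the continuous-area
#' dispersal ratio `(total_radius / core_radius)^2` is recovered up to
#' rasterization error.
#'
#' @param core_radius_px core radius, pixels (> 0).
#' @param total_radius_px total dispersal radius, pixels (>= core).
#' @param img_px square grid side; defaults to fit the total disk.
#' @param seed kept for API uniformity; the masks are deterministic.
#' @return list: `core_mask`, `total_mask`, `truth`.
#' @export
gen_spheroid_masks <- function(core_radius_px = 20, total_radius_px = 40,
                               img_px = NULL, seed = 1) {
  stopifnot(core_radius_px > 0, total_radius_px >= core_radius_px)
  if (is.null(img_px)) img_px <- 2 * ceiling(total_radius_px) + 5
  ctr <- c((img_px + 1) / 2, (img_px + 1) / 2)
  cc <- expand.grid(row = seq_len(img_px), col = seq_len(img_px))
  d2 <- (cc$col - ctr[1])^2 + (cc$row - ctr[2])^2
  core <- region_mask(cbind(cc$row[d2 <= core_radius_px^2],
                            cc$col[d2 <= core_radius_px^2]),
                      c(img_px, img_px), 1L)
  total <- region_mask(cbind(cc$row[d2 <= total_radius_px^2],
                             cc$col[d2 <= total_radius_px^2]),
                       c(img_px, img_px), 2L)
  truth <- list(core_radius_px = core_radius_px,
                total_radius_px = total_radius_px,
                continuous_ratio = (total_radius_px / core_radius_px)^2,
                img_px = img_px, seed = seed)
  list(core_mask = core, total_mask = total, truth = truth)
}

#' Generate detachment-kinetics count tables
#'
#' First-order detachment: at time t the detached count is
#' `Binomial(n_cells, 1 - exp(-rate * t))`; the residual is the remainder
#' (recovered by the second, complete trypsinization).
#'
#' @param n_cells cells per dish.
#' @param rate_per_min detachment rate constant (> 0).
#' @param times_min assay times in minutes.
#' @param seed RNG seed.
#' @return list: `counts` (data.frame `time_min`, `detached`, `residual`),
#'   `truth` (including the closed-form expected fractions).
#' @export
gen_detachment_counts <- function(n_cells = 1000, rate_per_min = 0.5,
                                  times_min = c(1, 2, 5, 10), seed = 1) {
  stopifnot(rate_per_min > 0, n_cells >= 1, all(times_min >= 0))
  pdet <- 1 - exp(-rate_per_min * times_min)
  detached <- withr::with_seed(seed,
    stats::rbinom(length(times_min), n_cells, pdet))
  counts <- data.frame(time_min = times_min, detached = detached,
                       residual = n_cells - detached)
  truth <- list(n_cells = n_cells, rate_per_min = rate_per_min,
                times_min = times_min, expected_fraction = pdet, seed = seed)
  list(counts = counts, truth = truth)
}

#' Generate synthetic MTOC/nucleus configurations
#'
#' Draws per-cell MTOC orientation categories from the given probabilities
#' and places an MTOC point whose signed projection on the travel axis
#' realises the category under dead-band `tau_um` (with a 0.2 µm guard away
#' from the class boundary), plus a random lateral offset.
#'
#' @param n number of cells.
#' @param probs probabilities `(anterior, posterior, centroid)`, summing to 1.
#' @param tau_um dead-band half-width, µm.
#' @param frontline_direction `c(x, y)` towards the gap.
#' @param seed RNG seed.
#' @return list: `cells` (data.frame with nucleus centroid, MTOC point and
#'   true category per cell), `truth`.
#' @export
gen_mtoc_cells <- function(n = 300, probs = c(0.6, 0.25, 0.15), tau_um = 3,
                           frontline_direction = c(1, 0), seed = 1) {
  stopifnot(length(probs) == 3, all(probs >= 0), abs(sum(probs) - 1) < 1e-9,
            tau_um > 0, n >= 1)
  fd <- unit_vector(frontline_direction)
  lat <- perp_vector(fd)
  cells <- withr::with_seed(seed, {
    cat_i <- sample.int(3, n, replace = TRUE, prob = probs)
    proj <- numeric(n)
    guard <- 0.2
    for (i in seq_len(n)) {
      proj[i] <- switch(cat_i[i],
        tau_um + guard + stats::runif(1, 0, 3 * tau_um),       # anterior
        -(tau_um + guard + stats::runif(1, 0, 3 * tau_um)),    # posterior
        stats::runif(1, -(tau_um - guard), tau_um - guard))    # centroid
    }
    nuc <- cbind(stats::runif(n, 0, 100), stats::runif(n, 0, 100))
    lateral <- stats::runif(n, -2 * tau_um, 2 * tau_um)
    data.frame(
      nucleus_x = nuc[, 1], nucleus_y = nuc[, 2],
      mtoc_x = nuc[, 1] + proj * fd[1] + lateral * lat[1],
      mtoc_y = nuc[, 2] + proj * fd[2] + lateral * lat[2],
      projection_um = proj,
      category = mtoc_categories()[cat_i]
    )
  })
  truth <- list(n = n, probs = probs, tau_um = tau_um,
                frontline_direction = fd, seed = seed)
  list(cells = cells, truth = truth)
}
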