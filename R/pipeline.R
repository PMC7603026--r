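# Run-level orchestration: binds I/O, per-cell measures and statistics into
# the three standard analyses (scratch-assay morphometry, focal-adhesion
# quantification, migration-track statistics). Every run writes a manifest
# recording the full configuration, every defaulted parameter, and the
# package version, sufficient to reproduce the outputs byte-for-byte for
# deterministic stages.

#' Build a rectangular background region
#'
#' Convenience constructor for the signal-free background region used in
#' intensity measurements: an axis-aligned rectangle given as
#' `c(row1, col1, row2, col2)` (1-based, inclusive).
#'
#' @param rect integer vector `c(row1, col1, row2, col2)`.
#' @param dim grid dimensions `c(nrow, ncol)`.
#' @return a [region_mask].
#' @export
background_rect <- function(rect, dim) {
  stopifnot(length(rect) == 4)
  rows <- rect[1]:rect[3]
  cols <- rect[2]:rect[4]
  region_mask(as.matrix(expand.grid(row = rows, col = cols)), dim, 0L)
}

resolve_background <- function(background, dim) {
  if (inherits(background, "region_mask")) return(background)
  if (is.character(background)) return(read_masks(background)[[1]])
  if (is.numeric(background) && length(background) == 4)
    return(background_rect(background, dim))
  stop("missing or invalid background region: give a region_mask, a mask ",
       "file path, or c(row1, col1, row2, col2)")
}

write_manifest <- function(config, defaults, output_dir) {
  manifest <- list(
    tool = "cytomotion",
    version = as.character(utils::packageVersion("cytomotion")),
    config = config,
    defaulted_parameters = defaults
  )
  path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  path
}

take_default <- function(config, name, default, defaults_env) {
  if (is.null(config[[name]])) {
    defaults_env$d[[name]] <- default
    default
  } else config[[name]]
}

#' Run the scratch-assay morphometry analysis
#'
#' For each sample (one stained image plus matching cell and nucleus label
#' images, labels paired), computes the per-cell morphometry measures and
#' writes `morphometry.csv`, `summary.json` (per-condition population
#' summaries, plus one-way ANOVA with Tukey HSD per metric when at least
#' two conditions are present) and `manifest.json` into `output_dir`.
#'
#' @param config list with fields: `samples` (list of lists with
#'   `condition`, `image`, `cell_masks`, `nucleus_masks` paths), `pixel_size`,
#'   `background` (see [background_rect()]; a rectangle spec, mask path or
#'   [region_mask]), and optionally `frontline_direction` (default `c(1, 0)`,
#'   i.e. images oriented with the wound to the right), `channel_label`
#'   (default `"tubulin"`), `clip_negative` (default TRUE), `output_dir`.
#' @return invisibly, the per-cell results data.frame.
#' @export
run_morphometry <- function(config) {
  stopifnot(is.list(config), !is.null(config$samples), !is.null(config$pixel_size))
  denv <- new.env(); denv$d <- list()
  fd <- take_default(config, "frontline_direction", c(1, 0), denv)
  channel <- take_default(config, "channel_label", "tubulin", denv)
  clip <- take_default(config, "clip_negative", TRUE, denv)
  out_dir <- take_default(config, "output_dir", ".", denv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (s in config$samples) {
    img <- read_image(s$image, config$pixel_size, channel)
    cells <- read_masks(s$cell_masks)
    nucs <- read_masks(s$nucleus_masks)
    bg <- resolve_background(config$background, dim(img$pixels))
    nuc_by_label <- stats::setNames(nucs, vapply(nucs, function(m) m$label, 0L))
    for (cm in cells) {
      nm <- nuc_by_label[[as.character(cm$label)]]
      if (is.null(nm))
        stop("cell label ", cm$label, " has no matching nucleus mask in ",
             s$nucleus_masks)
      rec <- cell_record(cm, nm, stats::setNames(list(img), channel), fd)
      res <- tryCatch(
        measure_cell(rec, bg, channel = channel, clip_negative = clip),
        error = function(e) stop("cell ", cm$label, " (", s$condition, "): ",
                                 conditionMessage(e)))
      rows[[length(rows) + 1]] <- cbind(
        data.frame(condition = s$condition, cell_id = cm$label), res)
    }
  }
  results <- do.call(rbind, rows)
  utils::write.csv(results, file.path(out_dir, "morphometry.csv"),
                   row.names = FALSE)
  write_group_summary(results, c("area_um2", "polarity_um", "total_intensity",
                                 "mean_intensity", "angle_deg"),
                      file.path(out_dir, "summary.json"))
  write_manifest(config, denv$d, out_dir)
  invisible(results)
}

#' Run the migration-track analysis
#'
#' Reads one track CSV per condition, computes per-cell migration
#' statistics and writes `track_stats.csv`, `summary.json` and
#' `manifest.json` into `output_dir`.
#'
#' @param config list with fields: `tracks` (named list
#'   `condition = csv_path`), and optionally `pixel_size` (default 1),
#'   `frame_interval` minutes (default 12), `output_dir`.
#' @return invisibly, the per-cell statistics data.frame.
#' @export
run_tracks <- function(config) {
  stopifnot(is.list(config), !is.null(config$tracks), length(config$tracks) >= 1)
  if (is.null(names(config$tracks)) || any(names(config$tracks) == ""))
    stop("'tracks' must be a named list: condition = csv path")
  denv <- new.env(); denv$d <- list()
  pixel_size <- take_default(config, "pixel_size", 1, denv)
  fi <- take_default(config, "frame_interval", 12, denv)
  out_dir <- take_default(config, "output_dir", ".", denv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(config$tracks), function(cond) {
    tt <- read_tracks(config$tracks[[cond]], fi)
    cbind(condition = cond, track_stats_all(tt, pixel_size))
  })
  results <- do.call(rbind, rows)
  utils::write.csv(results, file.path(out_dir, "track_stats.csv"),
                   row.names = FALSE)
  write_group_summary(results, c("accumulated_um", "euclidean_um",
                                 "directionality", "velocity_um_per_h"),
                      file.path(out_dir, "summary.json"))
  write_manifest(config, denv$d, out_dir)
  invisible(results)
}

#' Run the focal-adhesion analysis
#'
#' For each sample (vinculin-stained image plus cell label image), detects
#' puncta per cell and writes `fa_metrics.csv` (and optionally a
#' per-punctum table) plus `manifest.json` into `output_dir`.
#'
#' @param config list with fields: `samples` (list of lists with
#'   `condition`, `image`, `cell_masks`), `pixel_size`, `background`, and
#'   optionally `rel_threshold` (default 0.5), `min_area_px` (default 4),
#'   `connectivity` (default 8), `per_punctum` (default FALSE),
#'   `output_dir`.
#' @return invisibly, the per-cell metrics data.frame.
#' @export
run_adhesions <- function(config) {
  stopifnot(is.list(config), !is.null(config$samples), !is.null(config$pixel_size))
  denv <- new.env(); denv$d <- list()
  rel <- take_default(config, "rel_threshold", 0.5, denv)
  min_area <- take_default(config, "min_area_px", 4, denv)
  conn <- take_default(config, "connectivity", 8, denv)
  per_punctum <- take_default(config, "per_punctum", FALSE, denv)
  out_dir <- take_default(config, "output_dir", ".", denv)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$background)) stop("missing background region")
  rows <- list(); prows <- list()
  for (s in config$samples) {
    img <- read_image(s$image, config$pixel_size, "vinculin")
    cells <- read_masks(s$cell_masks)
    bg <- resolve_background(config$background, dim(img$pixels))
    for (cm in cells) {
      ps <- detect_puncta(img, cm, bg, rel_threshold = rel,
                          min_area_px = min_area, connectivity = conn)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(condition = s$condition, cell_id = cm$label),
        fa_metrics(ps))
      if (per_punctum && length(ps$regions)) {
        prows[[length(prows) + 1]] <- data.frame(
          condition = s$condition, cell_id = cm$label,
          punctum = seq_along(ps$regions), area_um2 = ps$area_um2,
          mean_intensity = ps$mean_intensity,
          mean_intensity_raw = ps$mean_intensity_raw)
      }
    }
  }
  results <- do.call(rbind, rows)
  utils::write.csv(results, file.path(out_dir, "fa_metrics.csv"),
                   row.names = FALSE)
  if (per_punctum && length(prows))
    utils::write.csv(do.call(rbind, prows),
                     file.path(out_dir, "fa_puncta.csv"), row.names = FALSE)
  write_manifest(config, denv$d, out_dir)
  invisible(results)
}

# per-condition summaries and, with >= 2 conditions, one-way ANOVA + Tukey
# per metric
write_group_summary <- function(results, metrics, path) {
  conds <- unique(results$condition)
  summaries <- lapply(conds, function(cond) {
    sub <- results[results$condition == cond, metrics, drop = FALSE]
    s <- population_summary(sub)
    stats::setNames(split(s[, c("mean", "sd", "sem", "n")], seq_len(nrow(s))),
                    s$metric)
  })
  names(summaries) <- conds
  out <- list(conditions = summaries)
  if (length(conds) >= 2) {
    tests <- list()
    for (m in metrics) {
      ok <- !is.na(results[[m]])
      if (length(unique(results$condition[ok])) < 2) next
      if (any(table(results$condition[ok]) < 2)) next
      tr <- oneway_anova_tukey(results[[m]][ok], results$condition[ok])
      tests[[m]] <- list(F = tr$statistic, df = as.numeric(tr$df),
                         p = tr$p_value, tukey = tr$pairwise)
    }
    out$tests <- tests
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, dataframe = "rows", null = "null")
  invisible(path)
}
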