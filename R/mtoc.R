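# MTOC orientation relative to nucleus and leading edge.
#
# In a polarized migrating cell the microtubule-organizing center sits
# between the nucleus and the leading edge ("anterior"); perturbed cells
# show "posterior" (between nucleus and cell rear) or "centroid" (at the
# nucleus) configurations. The classifier projects the nucleus-to-MTOC
# vector onto the travel axis and applies a dead-band of half-width tau.

#' Classify MTOC position relative to the nucleus
#'
#' Computes the signed projection `p` of the nucleus-to-MTOC vector onto
#' the frontline direction (towards the gap) and classifies:
#' `anterior` if `p > tau_um`, `posterior` if `p < -tau_um`, `centroid`
#' otherwise. Lateral displacement is ignored. A sensible default for
#' `tau_um` is the nucleus equivalent radius, `sqrt(area / pi)` — "centroid"
#' then means the MTOC lies within the nuclear footprint along the travel
#' axis (see [nucleus_equivalent_radius()]).
#'
#' @param nucleus_centroid `c(x, y)` nucleus centre, micrometres.
#' @param mtoc_point `c(x, y)` MTOC position, micrometres.
#' @param frontline_direction `c(x, y)` pointing from the monolayer into the
#'   cell-free gap (normalised internally).
#' @param tau_um dead-band half-width in micrometres (>= 0).
#' @return list with `category` (factor: anterior/posterior/centroid) and
#'   `signed_projection_um`.
#' @export
classify_mtoc <- function(nucleus_centroid, mtoc_point, frontline_direction,
                          tau_um) {
  if (is.null(mtoc_point)) stop("MTOC point is missing")
  stopifnot(length(nucleus_centroid) == 2, length(mtoc_point) == 2,
            is.numeric(tau_um), length(tau_um) == 1, tau_um >= 0)
  fd <- unit_vector(frontline_direction)
  p <- sum((as.numeric(mtoc_point) - as.numeric(nucleus_centroid)) * fd)
  category <- if (p > tau_um) "anterior" else if (p < -tau_um) "posterior" else "centroid"
  list(category = factor(category, levels = mtoc_categories()),
       signed_projection_um = p)
}

#' @rdname classify_mtoc
#' @export
mtoc_categories <- function() c("anterior", "posterior", "centroid")

#' Dead-band default: nucleus equivalent radius
#'
#' Radius of the circle with the nucleus mask's area, `sqrt(area / pi)`,
#' in micrometres.
#'
#' @param nucleus_mask a [region_mask].
#' @param pixel_size micrometres per pixel.
#' @return radius in micrometres.
#' @export
nucleus_equivalent_radius <- function(nucleus_mask, pixel_size) {
  sqrt(cell_area(nucleus_mask, pixel_size) / pi)
}

#' Frequency distribution of MTOC orientation classes
#'
#' Fractions of cells per category. The last fraction is computed as one
#' minus the others so the three values sum to exactly 1.
#'
#' @param classifications character/factor vector of categories, or a list
#'   of [classify_mtoc()] results.
#' @return named numeric vector `(anterior, posterior, centroid)` summing to
#'   1, with attribute `counts`.
#' @export
orientation_frequencies <- function(classifications) {
  if (is.list(classifications) && !is.null(classifications[[1]]$category))
    classifications <- vapply(classifications,
                              function(z) as.character(z$category), "")
  classifications <- as.character(classifications)
  if (length(classifications) == 0) stop("no classifications supplied")
  bad <- setdiff(unique(classifications), mtoc_categories())
  if (length(bad)) stop("unknown category: ", paste(bad, collapse = ", "))
  counts <- table(factor(classifications, levels = mtoc_categories()))
  n <- sum(counts)
  freqs <- as.numeric(counts) / n
  freqs[length(freqs)] <- 1 - sum(freqs[-length(freqs)])
  names(freqs) <- mtoc_categories()
  attr(freqs, "counts") <- as.integer(counts)
  freqs
}
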