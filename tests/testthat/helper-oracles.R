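# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops, rotation matrices, and brute-force
# enumeration.

# Minimum-area enclosing rectangle by explicit search: for every convex-hull
# edge, rotate ALL points with a rotation matrix so the edge is horizontal
# and take the axis-aligned bounding box. Returns the minimal area.
oracle_min_rect_area <- function(pts) {
  pts <- as.matrix(pts)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  n <- nrow(hull)
  best <- Inf
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    ang <- atan2(hull[j, 2] - hull[i, 2], hull[j, 1] - hull[i, 1])
    R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
    rot <- pts %*% t(R)
    area <- diff(range(rot[, 1])) * diff(range(rot[, 2]))
    if (area < best) best <- area
  }
  best
}

# Pixels of a digital disk by brute-force loop over the grid
# (center-in-circle rule); returns the count.
oracle_disk_pixel_count <- function(cx, cy, r, nrow, ncol) {
  count <- 0
  for (row in seq_len(nrow)) {
    for (col in seq_len(ncol)) {
      if ((col - cx)^2 + (row - cy)^2 <= r^2) count <- count + 1
    }
  }
  count
}

# Random convex-position point cloud: points on a noisy ellipse plus
# interior fill, guaranteed non-collinear.
random_point_cloud <- function(n = 40) {
  a <- runif(1, 5, 30); b <- runif(1, 3, 20); th <- runif(1, 0, pi)
  t <- runif(n, 0, 2 * pi); r <- sqrt(runif(n))
  x0 <- a * r * cos(t); y0 <- b * r * sin(t)
  cbind(x = x0 * cos(th) - y0 * sin(th) + runif(1, -50, 50),
        y = x0 * sin(th) + y0 * cos(th) + runif(1, -50, 50))
}

# Independent persistent-random-walk simulator (no bias): Gaussian turn
# angles with sd sqrt(-2 log p); returns per-track directionality.
oracle_prw_directionality <- function(n_tracks, n_steps, persistence) {
  vapply(seq_len(n_tracks), function(i) {
    theta <- runif(1, 0, 2 * pi)
    x <- 0; y <- 0; acc <- 0
    for (s in seq_len(n_steps)) {
      theta <- if (persistence > 0) theta + rnorm(1, 0, sqrt(-2 * log(persistence)))
               else runif(1, 0, 2 * pi)
      x <- x + cos(theta); y <- y + sin(theta); acc <- acc + 1
    }
    sqrt(x^2 + y^2) / acc
  }, 0)
}

# two-sided binomial confidence bounds for an observed proportion
binom_bounds <- function(p, n, conf = 0.99) {
  z <- qnorm(1 - (1 - conf) / 2)
  c(p - z * sqrt(p * (1 - p) / n), p + z * sqrt(p * (1 - p) / n))
}

# build a region_mask from a filled pixel rectangle (1-based, inclusive)
rect_mask <- function(r1, c1, r2, c2, dim, label = 1L) {
  region_mask(as.matrix(expand.grid(row = r1:r2, col = c1:c2)), dim, label)
}
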