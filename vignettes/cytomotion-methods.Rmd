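---
title: "Methods: quantifying motility and cytoskeletal organization in scratch assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying motility and cytoskeletal organization in scratch assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomotion)
```

# Scope and measurement model

cytomotion quantifies the phenotypic readouts of wound-healing (scratch)
assays and related adhesion/invasion assays: per-cell geometry and
fluorescence, MTOC polarity, focal-adhesion patterns, single-cell
migration statistics, spheroid dispersal, and detachment kinetics.
Segmentation is deliberately out of scope: cells and nuclei are segmented
upstream (typically manually in an image tool) and enter as labeled mask
images; the package's job is everything after segmentation, with explicit
units and reproducible parameters.

All geometry is computed on pixel-centre point sets: pixel `(r, c)` is
the point `(x = c, y = r)` (1-based, origin top-left). This makes toy
cases exact — a mask 10 pixels wide has a point-set extent of 9 — and is
stated on every writer. We use R's native 1-based indices throughout
(external CSV coordinates included) rather than a 0-based convention;
mixing bases across a matrix-indexing language invites off-by-one errors,
and no physical quantity depends on the base.

## Frontline and angle convention

The *frontline* is the wound-edge line; the stored reference is the unit
`frontline_direction` pointing from the monolayer into the cell-free gap,
and the frontline axis is its perpendicular. A cell's orientation is the
angle between the long edge of its minimal-area bounding rectangle and
the frontline axis, reduced modulo 180° and reflected so the result lies
in [0°, 90°]: 0° means elongated along the wound edge, 90° elongated
along the travel direction. Some figure styles label the leading edge
90°; `frontline_angle(..., complement = TRUE)` reports `90 - angle` for
those plots without changing the stored convention.

The minimal bounding rectangle is found by rotating calipers: the optimal
rectangle has a side collinear with a convex-hull edge, so each hull edge
is examined and the smallest-area rectangle kept. Ties in area are broken
towards the smaller long-edge angle to the x-axis. A square rectangle has
no meaningful orientation; the angle is reported as 0° with a warning. An
input whose pixel centres are collinear admits no rectangle of positive
width and is rejected with an error.

**Resolution matters for the orientation readout.** The rectangle's
long-edge direction can only take the directions of digitized hull edges,
which are rational slopes; on small masks the estimate therefore snaps a
few degrees away from the true axis, and the error does not vanish
smoothly with modest resolution increases. Recovery to ~2° needs the
major axis to span a few hundred pixels. The synthetic generator's
default calibration (0.1 µm/pixel, semi-minor axis 20 µm, axis ratio 2,
i.e. a 400-pixel major axis) was chosen to emulate a 63x oil objective at
high zoom on large glioblastoma leading-edge cells and satisfies this;
users quantifying orientation on coarser data should expect coarser
angles.

## Per-cell measures

* **Area**: pixel count × pixel_size², µm².
* **Polarity distance**: Euclidean distance between the nucleus-mask
  centroid and the cell-mask centroid, µm. "Centre of mass" is the
  geometric centroid of the binary mask — segmentation defines the cell,
  not its brightness; an intensity-weighted variant would couple the
  polarity measure to staining efficiency.
* **Intensity**: the background level is the mean over a user-chosen
  signal-free region; it is subtracted per pixel before summing over the
  cell. Negative differences are clipped to zero by default (fluorescence
  cannot be negative); the clip is toggleable and the raw sums are always
  reported alongside, since whether a "total intensity" readout should be
  background-subtracted is a reporting choice, not a fact of the data.

## MTOC polarity

In a polarized migrating cell the MTOC sits between nucleus and leading
edge. We operationalize the three classes by the signed projection *p* of
the nucleus-to-MTOC vector onto the travel direction with a dead band τ:
anterior if *p* > τ, posterior if *p* < −τ, centroid otherwise. Lateral
displacement is ignored — the classes are front/rear language. τ is a
required, logged parameter; the recommended default is the nucleus
equivalent radius `sqrt(area/π)`, under which "centroid" means the MTOC
lies within the nuclear footprint along the travel axis. Whether the
underlying biology partitions by projection or by angular sectors is not
decidable from class labels alone; the projection rule is the documented
choice. Reported frequencies use exact count arithmetic, with the last
class computed as one minus the others so the three fractions sum to
exactly 1.

## Focal adhesions

No universal segmentation rule exists for vinculin puncta; the package's
documented default thresholds at
`background mean + rel_threshold × (in-cell maximum − background mean)`
(default `rel_threshold = 0.5`), takes 8-connected components within the
cell mask, and keeps components of ≥ `min_area_px` pixels (default 4).
Anchoring both ends of the threshold to measured levels makes detection
invariant to constant illumination offsets, which is tested. Raising the
threshold can only shrink the pixel set, so counts are monotone
non-increasing in `rel_threshold` (also tested). Touching puncta are not
split — no watershed — a declared limitation; the validation suite only
plants separated puncta. A flat image yields an empty set, not an error.
Connected-component labeling is implemented in-package (two-pass
union-find) because the default connectivity is 8 and must be
configurable; it is cross-checked against EBImage's labeler where
connectivities coincide.

## Migration statistics

For a track of positions at a fixed frame interval (default 12 min, the
standard time-lapse cadence for these assays): accumulated distance is
the sum of step lengths; Euclidean distance the start-to-end length;
directionality their ratio (1 = straight, undefined and reported as `NA`
for a stationary track); velocity is accumulated distance over elapsed
time, matching the common chemotaxis-tool convention, with the
straight-line variant exposed separately as `straight_speed_um_per_h` so
the two are never conflated. Elapsed time is `(n_frames − 1) ×
frame_interval`. The SD of a single observation is reported as missing,
never 0. The wound-edge migration rate is the OLS slope of edge advance
against time; edge extraction from images is out of scope and the series
is an input.

## Scalar assays

Dispersal ratio = total outgrowth area / spheroid core area, computed on
filled traced regions (interior holes count as area — the traced outline
is the biological boundary); it is dimensionless, hence independent of
pixel calibration. Detachment fraction = detached / (detached + residual)
per stated trypsinization time; times are stored explicitly rather than
hard-coding per-cell-line durations. A diagnostic log-linear fit
(`log(1 − fraction)` through the origin) recovers a first-order rate for
the synthetic kinetics; no curve fitting beyond this diagnostic is
offered because the assay readout is the fraction itself.

## Inference

The reported tests are a paired t-test, one-way ANOVA with Tukey HSD, and
two-way ANOVA with Tukey HSD, all two-sided, delegated to R's standard
implementations behind a uniform result type. Two-way designs must be
complete and balanced — with equal cell sizes the sums-of-squares
decomposition is unambiguous, avoiding an arbitrary Type I/III choice;
unbalanced input is rejected rather than silently reinterpreted. A factor
with one level degrades to the one-way analysis. An effect whose sum of
squares is zero up to floating-point noise (judged against the squared
response scale) reports F = 0, p = 1 instead of 0/0. The pairing key of
the paired test is the caller's responsibility (`x[i]` with `y[i]`).
Calibration is verified empirically: under simulated Gaussian nulls the
type-I error of the paired t-test and of the ANOVA, and the family-wise
error of Tukey HSD, must fall within the binomial 99% interval of the
nominal α = 0.05, and the two-group F must equal the squared pooled t.

# The synthetic-data generators

Every generator is seeded (`withr::with_seed`, leaving the global RNG
untouched), bit-reproducible, and returns a ground-truth sidecar that
fully determines the artifact. They emulate the *structure* of the real
inputs, not their appearance:

* `gen_cell_image` — a rasterized ellipse (center-in rule) at a known
  angle to the frontline, a circular nucleus offset along the rear axis
  (polarized cells carry the nucleus rearward), and a tubulin-like
  channel of background + amplitude + Gaussian noise quantized to 16-bit.
  The default background (100 counts) is a realistic detector offset and
  keeps the declared Gaussian noise self-consistent: with a near-zero
  background the zero-clip of quantization would truncate the noise and
  bias background estimates. Poisson shot noise is available as an
  option. Defaults: amplitude 120, noise SD 6 (SNR 20), 0.1 µm/pixel.
* `gen_fa_image` — disjoint bright disks (default radius 3 px, spacing
  ≥ 10 px, amplitude 200, noise SD 8) planted in a circular cell by
  rejection sampling; infeasible packings error out after a bounded
  number of attempts.
* `gen_tracks` — a persistent random walk with constant step length:
  each heading is the previous one rotated by a Gaussian turn angle of SD
  `sqrt(−2 log p)`, so the lag-1 autocorrelation of step directions
  equals the persistence `p` exactly (`p = 0` draws uniform headings);
  optional drift towards a bias direction, and a demonstration-only
  option that rotates the bias 90° on a schedule, mimicking an
  alternating-field cadence without claiming a mechanistic field-coupling
  model.
* `gen_spheroid_masks`, `gen_detachment_counts`, `gen_mtoc_cells` —
  concentric digital disks; binomial draws from `1 − exp(−kt)`; and
  MTOC/nucleus pairs drawn from given class probabilities with a 0.2 µm
  guard away from the class boundary.

**What passing recovery tests shows — and does not.** The generators
contain no segmentation error, no uneven illumination, no touching
adhesions, no out-of-focus light, and elliptical cells only. Recovery of
planted parameters therefore validates the measurement code and its
conventions, not robustness to real microscopy artifacts; on real data
the dominant error source will usually be the upstream segmentation,
which this package consumes as given.

# Numerical choices and degenerate inputs

* Integer intensities round-trip exactly for 8/16-bit TIFF and 8/16-bit
  PNG input (PNG bit depth read from the file header); PNG output is
  8-bit, 16-bit data goes to TIFF. Track CSVs are written with `%.17g`
  so coordinates round-trip bit-for-bit.
* Bounding-rectangle area ties break towards the smaller angle;
  equality uses a 1e-12 absolute guard on areas.
* A stationary track reports `NA` directionality and zero velocity; a
  flat adhesion image reports zero puncta; `orientation_frequencies`
  rejects empty input.
* Validation sizes used by the shipped tests: 100 random point clouds
  for the geometry oracle, 50 synthetic cells for image recovery, 20
  punctum images, 500 tracks per persistence level, and 10⁴-replicate
  nulls for test calibration — sizes at which the Monte-Carlo intervals
  are tight enough to be informative while the whole suite stays quick.

# Known limitations

Manual segmentation is assumed correct and is not audited; touching
focal adhesions are merged; the orientation readout needs high-resolution
masks (above); 3D stacks and proprietary microscope formats are not read;
the bias-modulation track option is a demonstration, not a calibrated
field-response model; and the two-way ANOVA deliberately refuses
unbalanced designs rather than choosing a sums-of-squares convention
silently.
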