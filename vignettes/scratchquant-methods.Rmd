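---
title: "Methods: automated scratch-assay quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated scratch-assay quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the measurement model behind `scratchquant`, the
parameters that matter, the synthetic data the package validates itself
on, and the numerical and design choices a maintainer should know about.

## The measurement model

A scratch assay image is modelled as a two-class scene: *cell* pixels
(textured, edge-rich monolayer) and *media* pixels (optically flat,
cell-free background, including the scratch itself). The pipeline makes
four reductions, each feeding the next:

**1. Gradient-magnitude binarization.** The image is smoothed with an
isotropic Gaussian (`smoothing_sigma`, default 1 px) and the per-pixel
Euclidean gradient magnitude is computed by central differences
(one-sided at borders). Cells carry high gradient (membrane edges,
intracellular texture); media carries almost none. The magnitude map is
thresholded — Otsu's method on its 256-bin histogram by default, or a
fixed value for reproducibility pinning — so that *edge pixels are coded
as cell* (white) directly by construction. Morphological closing with a
disc (`closing_radius`, default 5 px) and hole filling then convert
low-gradient cell interiors to white, and white components smaller than
`min_object_area` (default 64 px²) are discarded as noise. The cleanup
order (closing → hole fill → small-object removal) is deliberate: closing
first merges edge fragments into closed contours so that hole filling can
reach intracellular flat zones, and area filtering last removes only what
survived neither step.

The key assumption is textural: segmentation will misclassify genuinely
flat cell interiors larger than the closing scale, and any textured
debris in the media. No per-cell instance segmentation or tracking is
attempted.

**2. Column profiles.** Each mask column (image width W, e.g. 1600
columns at 1600 × 1200 px) is summarized by its black fraction
(black / column height, in [0, 1]) and its black-to-white pixel ratio.
The black fraction is the primary statistic because it is bounded and
averages cleanly across replicates; the B/W ratio is reported for
fidelity to the field's convention but is infinite exactly where a
column is all black — which is precisely the state of the scratch columns
at hour 0 — so ratios are flagged and excluded from averaging rather than
averaged.

**3. Disruption-center alignment.** The scratch position varies between
fields, so profiles are aligned before comparison or averaging. The
center is defined on the hour-0 profile: the midpoint of the longest
contiguous run of all-black columns (lower median for even-length runs;
ties between equally long runs resolve to the leftmost — both rules are
arbitrary but deterministic). If no all-black column exists the profile
is smoothed with a 51-column moving average and its argmax is used, with
a warning, since the disruption is then only partial; if the maximum
black fraction is below 0.5 there is no credible disruption and an error
is raised. Every profile of a replicate series — including later hours —
is shifted by an integer column offset placing its hour-0 center at
`floor(target_width/2) + 1` on a common axis. Columns shifted off the
axis are dropped; axis columns with no source are missing (`NA`), never
zero-filled, because a zero black fraction would masquerade as fully
cellular. No interpolation is performed: alignment is exact index
bookkeeping, and a shift-back reproduces the original on the overlap.

**4. Endpoints.** The hour-0 *gap region* is the maximal contiguous run
of columns with black fraction ≥ `gap_threshold` (default 0.95, not 1.0,
so isolated stray white pixels cannot fragment the run) containing the
detected center. Endpoints at each hour are: the gap width (the
thresholded run nearest the inherited hour-0 center, 0 once nothing
remains within `search_halfwidth` = 100 columns of it); percent closure
100·(1 − width_t/width_0); and the cell-to-space ratio, the white:black
pixel ratio inside the *hour-0* region, with its bounded transform the
occupied fraction = ratio/(1 + ratio). Measuring later hours inside the
hour-0 region (rather than re-deriving a region per hour) is a design
choice: it asks "how much of the original wound is now occupied", which
is the biologically interpretable quantity, and it keeps the denominator
fixed. The region definition (initial gap, not whole image) is likewise a
package decision and is documented rather than asserted as universal.

Replicate averaging operates on per-column black fractions, not on
pixel-wise averaged images. Averaging binarized images first and
re-thresholding would be the main alternative; per-column averaging was
chosen because it keeps each replicate's segmentation independent and
yields well-defined per-column standard errors and replicate counts.

## Fluorescence readouts

**Spot counting** uses multi-scale Laplacian-of-Gaussian detection: the
scale-normalized response σ²∇²(G_σ ∗ I) is computed on a log-spaced scale
ladder (`min_sigma` 2 px to `max_sigma` 8 px, 8 scales — sized for bright
roundish objects of ~5–15 px diameter), maximized over scale per pixel,
and 2-D local maxima above `detect_threshold` (default 0.05 on [0, 1]
intensities; a spot of peak amplitude A at its matched scale responds at
about A/2, so the default detects peaks down to A ≈ 0.1) are kept after
greedy non-maximum suppression at `min_separation` (default 5 px,
stronger response wins). The ROI is applied *after* detection, so a
count inside an ROI equals the restriction of the full-image detection —
which makes counts additive over partitions. The ROI itself must be
user-supplied: where to count relative to a wound is an experimental
decision, not an image property.

**Area fraction** is thresholded pixel counting: the fraction of pixels
above `signal_threshold`, and the above-threshold count divided by a
user-supplied nucleus count. Fold changes between conditions are ratios
of per-nucleus signals, which normalizes away field-to-field cell-number
differences.

## Group statistics

Endpoints are summarized as mean ± SE per condition. Comparisons follow
the assay field's convention: one-way ANOVA with Tukey's HSD for more
than two conditions, a two-sample t-test for exactly two, significance at
p ≤ alpha (default 0.05). The t-test is Student's pooled-variance by
default — chosen so that for two balanced groups ANOVA F equals t², a
relationship the test suite asserts to 1e-9 — with Welch available via
`var_equal = FALSE`; whether a given study's historical t-tests were
pooled or Welch is usually unstated, and the package does not guess. One
degenerate case is handled by convention: when both groups have zero
variance, `t.test` fails, so equal means yield t = 0, p = 1 and unequal
means yield p = 0 (a planted-truth fixture with perfect detection
produces exactly this case).

## The synthetic generator

`generate_scratch_series()` emulates what the measurement model needs
from a phase-contrast scratch image, nothing more: a confluent monolayer
rendered as a textured sheet (mean intensity `cell_base` 0.5, Gaussian
texture field of sd `texture_contrast` 0.2, correlation length ~1.5 px)
decorated with randomly placed elliptical cells (`cell_density` 8 per
10⁴ px², semi-axes 8–16 px) whose bright rims (0.85) give the gradient
operator realistic contrast structure — blank-interior cells would be
misclassified by design. Media is flat (0.25). The scratch is a vertical
band of planted center and width (defaults 800 and 200 columns on a
1600 × 1200 canvas, mirroring common acquisition geometry); closure is
emulated by filling the band from both edges inward with the same
textured sheet until the planted per-hour fill fraction (defaults 0, 0.5,
0.9 at 0, 24, 48 h) is reached. Gaussian pixel noise (`noise_sd`, default
0.02) is added last. A single seed governs everything; per-hour sub-seeds
are derived deterministically, so identical parameters give bit-identical
rasters.

The truth `cell_mask` is columnar: cells occupy full-height bands, so the
occupied fraction in the gap is exact by construction and the planted
center/width are recoverable by a brute-force column scan. This is the
main idealization. Real scratch edges are ragged, closure is not
symmetric, cells migrate individually rather than as a advancing column,
and phase-contrast optics produce halo artifacts none of which the
generator models. Passing tests therefore demonstrate that the *pipeline
recovers planted truth under its own assumptions* (textured cells, flat
media, columnar gap); they do not certify performance on real images with
broken assumptions, e.g. media-side debris or low-texture cell lines.

`generate_spot_image()` plants isotropic Gaussian bumps (σ 3 px, peak
0.8) on a constant background with a minimum pairwise separation
(default 30 px) and reports exact centers — sized so that the default
detector should achieve recall = precision = 1, which is what the
acceptance checks assert.

## Numerical choices and degenerate inputs

- Indexing is R's 1-based (row, column) convention everywhere; the common
  axis center is `floor(target_width/2) + 1`.
- A perfectly uniform image has a degenerate (single-valued) gradient
  histogram; it yields an all-black mask with a warning, not an error —
  a media-only field is a legitimate observation.
- Mask cleanup is idempotent (tested), so re-running it cannot drift.
- Lowering a fixed threshold can only grow the pre-cleanup white count
  (monotonicity, tested).
- CSV outputs are written with 6 significant digits so that repeated runs
  are byte-identical and diffable across platforms.
- Pixel-count comparisons against brute-force oracles are asserted to
  1e-12; they are integer ratios and agree exactly in practice.

## Problem sizes used in validation

The test suite exercises unit-level properties on small random masks
(≤ 64 × 64, 100 draws for the oracle-equivalence checks) and small
simulated scenes (400 × 300, gap width 80) where full-scale realism adds
nothing; end-to-end recovery, segmentation IoU (≥ 0.90 asserted; ~0.998
measured) and closure monotonicity run on ten full-size 1600 × 1200
fixtures at default noise plus ten noiseless ones; spot detection on ten
fixtures of 25 spots; the type-I calibration on 1000 simulated null
tables of 3 × 5 observations (acceptance band 0.03–0.07 at alpha 0.05).
These sizes were chosen so the whole validation completes in a few
minutes on a single core while still covering the full-scale geometry.

## Known limitations

- Column-wise profiling assumes a *vertical* scratch; a tilted or curved
  wound blurs the profile shoulders and biases the width low. Rotating
  the input is the user's responsibility.
- The gap-region threshold couples the width estimate to segmentation
  edge behavior: bordering cell edges coded white narrow the detected gap
  by a few columns (the recovered width of a planted 200-column scratch
  is typically 196).
- The B/W ratio is reported per column but never averaged where
  undefined; consumers reading the CSVs should treat `Inf` as "no white
  pixels in this column", not as a number.
- Spot counting assumes roughly isotropic blobs within the scale ladder;
  elongated or touching objects are merged or split by design of the LoG
  operator, and no attempt is made to classify spot identity.
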