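# scratchquant

Automated quantification of in vitro scratch (wound-healing) assays, plus
the fluorescence readouts that commonly accompany them.

In a scratch assay, a straight gap is scraped into a confluent cell
monolayer and migration into the gap is followed over time (typically 0,
24 and 48 h). Manual measurement of gap closure is slow and subjective.
`scratchquant` implements a fully automated pipeline:

1. **Segmentation** — each greyscale phase-contrast image is binarized by
   *gradient-magnitude quantification*: the per-pixel norm of the smoothed
   intensity gradient ‖∇(G_σ ∗ I)‖ is thresholded (Otsu by default), so
   cell edges and intracellular texture become white (cell) pixels and flat
   media becomes black; morphological closing and hole filling turn cell
   interiors white.
2. **Column profiling** — each mask (e.g. 1600 × 1200 px) is reduced to a
   per-column black fraction and black-to-white (B/W) pixel ratio across
   its 1600 columns.
3. **Re-centering and averaging** — the scratch center is detected at hour
   0 as the midpoint of the longest run of all-black columns; every
   replicate and time point is shifted onto a common axis anchored at that
   center, and profiles are averaged across replicates with per-column
   standard errors.
4. **Endpoints** — gap width, percent closure
   100·(1 − width_t / width_0), and the cell-to-space ratio (white:black
   pixels inside the hour-0 gap region, with its bounded companion, the
   occupied fraction).
5. **Fluorescence readouts** — multi-scale Laplacian-of-Gaussian spot
   counting inside a rectangular ROI (e.g. labelled neutrophils at a wound
   site) and thresholded area-fraction-per-nucleus immunofluorescence
   morphometry.
6. **Statistics** — group summaries as mean ± SE, one-way ANOVA with Tukey
   HSD for multi-group comparisons, pairwise t-tests for two groups,
   significance at p ≤ 0.05.

A synthetic image generator plants scratches of known center, width and
closure schedule (and fluorescence spots of known position), so every
stage is validated against ground truth.

## Worked example

Simulate one replicate (1600 × 1200 px, scratch of width 200 centered at
column 800, fill fractions 0 / 0.5 / 0.9 at 0 / 24 / 48 h), then run the
analysis:

```r
library(scratchquant)

params <- scratch_sim_params(seed = 7)
series <- generate_scratch_series(params)

mask0 <- binarize(series[["0"]]$image)
mask0
#> <binary_mask> 1600 x 1200 px  white (cell) fraction 0.876

profile0 <- column_profile(mask0)
center  <- find_gap_center(profile0)          # 800
region  <- gap_region_from_t0(profile0, center)
region
#> <gap_region> columns [703, 898], width 196

gap_metrics(lapply(series, function(fr) binarize(fr$image)))
#>  condition replicate hour gap_width_px closure_percent cell_to_space_ratio
#>  synthetic         1    0          196         0.00000           0.0000000
#>  synthetic         1   24           96        51.02041           0.9751428
#>  synthetic         1   48           17        91.32653           8.9563984
#>  occupied_fraction
#>          0.0000000
#>          0.4937075
#>          0.8995621
```

The planted truth is recovered closely: the detected center is exactly
800; the hour-0 gap width of 196 is within 4 columns of the planted 200
(edge pixels of the bordering cells are coded as cell, slightly narrowing
the detected gap); and the occupied fraction inside the initial gap
(0.494 at 24 h, 0.900 at 48 h) tracks the planted fill fractions 0.5 and
0.9 to within 0.01. The cell-to-space ratio is the same measurement on the
ratio scale: 0.975 at 24 h means the initial wound area holds nearly equal
cell and free-space pixels.

Batch analysis is manifest-driven (`run_scratch_pipeline`,
`run_spot_pipeline`, or the CLI at `inst/cli/scratchquant.R`); outputs are
tidy CSVs, a statistics report, profile plots and a serialized run
configuration.

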