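mk_profile <- function(bf, hour = 0) {
  structure(list(black_fraction = bf, bw_ratio = ifelse(bf < 1, 0, Inf),
                 height = 100L, width = length(bf), condition = "c",
                 replicate = 1L, hour = hour, center = NA_integer_),
            class = "column_profile")
}

test_that("gap region is the thresholded run containing the center", {
  bf <- rep(0, 1600); bf[701:900] <- 1
  reg <- gap_region_from_t0(mk_profile(bf), center = 800L)
  expect_equal(c(reg$left, reg$right, reg$width), c(701L, 900L, 200L))
  # threshold 1.0 with a single qualifying column
  bf2 <- rep(0.97, 100); bf2[50] <- 1
  reg2 <- gap_region_from_t0(mk_profile(bf2), center = 50L, threshold = 1.0)
  expect_equal(reg2$width, 1L)
  # center below threshold
  expect_error(gap_region_from_t0(mk_profile(rep(0.5, 100)), center = 50L),
               "no gap at center")
  expect_error(gap_region_from_t0(mk_profile(rep(1, 10), hour = 24), 5L),
               "hour-0")
})

test_that("gap width tracks the run near the anchor and reports closure", {
  bf <- rep(0, 400); bf[151:250] <- 1
  expect_equal(gap_width(mk_profile(bf), center = 200L), 100L)
  # fully closed: nothing above threshold anywhere
  expect_equal(gap_width(mk_profile(rep(0.2, 400)), center = 200L), 0L)
  # a residual run near the anchor is found even if it no longer covers it
  bf3 <- rep(0, 400); bf3[230:260] <- 1
  expect_equal(gap_width(mk_profile(bf3), center = 200L), 31L)
  # a distant black band is not mistaken for the tracked scratch
  bf4 <- rep(0, 400); bf4[380:400] <- 1
  expect_equal(gap_width(mk_profile(bf4), center = 100L), 0L)
  expect_equal(closure_percent(56, 80), 30)
  expect_equal(closure_percent(0, 80), 100)
  expect_error(closure_percent(10, 0), "positive")
})

test_that("cell-to-space ratio matches brute-force counts and its identity", {
  reg <- structure(list(left = 3L, right = 7L, width = 5L),
                   class = "gap_region")
  # empty gap: all black in the region
  px <- matrix(TRUE, 10, 10); px[, 3:7] <- FALSE
  r <- cell_to_space_ratio(binary_mask(px), reg)
  expect_equal(r$cell_to_space_ratio, 0)
  expect_equal(r$occupied_fraction, 0)
  # half white in the region
  px[1:5, 3:7] <- TRUE
  r <- cell_to_space_ratio(binary_mask(px), reg)
  expect_equal(r$cell_to_space_ratio, 1)
  expect_equal(r$occupied_fraction, 0.5)
  # fully occupied -> infinite ratio, fraction 1
  px[, 3:7] <- TRUE
  r <- cell_to_space_ratio(binary_mask(px), reg)
  expect_identical(r$cell_to_space_ratio, Inf)
  expect_equal(r$occupied_fraction, 1)

  set.seed(33)
  for (i in 1:20) {
    h <- sample(5:30, 1); w <- sample(8:30, 1)
    m <- random_logical_mask(h, w, runif(1, 0.05, 0.95))
    l <- sample(seq_len(w - 2), 1); rgt <- sample(l:w, 1)
    reg <- structure(list(left = l, right = rgt, width = rgt - l + 1L),
                     class = "gap_region")
    oracle <- brute_region_counts(m, l, rgt)
    r <- cell_to_space_ratio(binary_mask(m), reg)
    expect_equal(r$white_px, oracle$white)
    expect_equal(r$black_px, oracle$black)
    expect_gte(r$occupied_fraction, 0); expect_lte(r$occupied_fraction, 1)
    if (is.finite(r$cell_to_space_ratio))
      expect_equal(r$occupied_fraction,
                   r$cell_to_space_ratio / (1 + r$cell_to_space_ratio),
                   tolerance = 1e-12)
  }
  expect_error(cell_to_space_ratio(binary_mask(matrix(TRUE, 4, 4)),
                                   structure(list(left = 2L, right = 9L),
                                             class = "gap_region")),
               "outside mask bounds")
})

test_that("per-replicate gap metrics close monotonically on noiseless series", {
  p <- small_sim_params(seed = 2, noise_sd = 0)
  series <- generate_scratch_series(p)
  masks <- lapply(series, function(fr) binarize(fr$image))
  met <- gap_metrics(masks)
  expect_equal(nrow(met), 3L)
  expect_equal(met$closure_percent[met$hour == 0], 0)
  expect_true(all(diff(met$gap_width_px[order(met$hour)]) <= 0))
  expect_true(all(diff(met$occupied_fraction[order(met$hour)]) > 0))
})
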