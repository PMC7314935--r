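test_that("column profiles match brute-force pixel counting", {
  # checkerboard: every column half black, B/W ratio 1
  chk <- binary_mask((row(matrix(0, 40, 60)) + col(matrix(0, 40, 60))) %% 2 == 0)
  pr <- column_profile(chk)
  expect_equal(pr$black_fraction, rep(0.5, 60))
  expect_equal(pr$bw_ratio, rep(1, 60))
  # all white -> zero black everywhere
  pr_w <- column_profile(binary_mask(matrix(TRUE, 10, 8)))
  expect_equal(pr_w$black_fraction, rep(0, 8))
  expect_equal(pr_w$bw_ratio, rep(0, 8))
  # all-black columns carry an infinite ratio, finite exactly where bf < 1
  px <- matrix(TRUE, 10, 5); px[, 3] <- FALSE
  pr_b <- column_profile(binary_mask(px))
  expect_identical(is.finite(pr_b$bw_ratio), pr_b$black_fraction < 1)

  set.seed(21)
  for (i in 1:20) {
    h <- sample(5:40, 1); w <- sample(5:40, 1)
    m <- random_logical_mask(h, w, runif(1, 0.1, 0.9))
    oracle <- brute_column_counts(m)
    pr <- column_profile(binary_mask(m))
    expect_equal(pr$black_fraction, oracle$black / h, tolerance = 1e-15)
    expect_equal(oracle$black + oracle$white, rep(h, w))  # conservation
    fin <- oracle$white > 0
    expect_equal(pr$bw_ratio[fin], (oracle$black / oracle$white)[fin],
                 tolerance = 1e-15)
  }
})

test_that("gap center is the midpoint of the longest all-black run", {
  mk_profile <- function(bf, hour = 0) {
    structure(list(black_fraction = bf, bw_ratio = ifelse(bf < 1, bf / (1 - bf), Inf),
                   height = 100L, width = length(bf), condition = "c",
                   replicate = 1L, hour = hour, center = NA_integer_),
              class = "column_profile")
  }
  bf <- rep(0, 1600); bf[701:901] <- 1          # run 701..901 -> midpoint 801
  expect_equal(find_gap_center(mk_profile(bf)), 801L)
  bf <- rep(0, 1600); bf[513] <- 1              # single all-black column
  expect_equal(find_gap_center(mk_profile(bf)), 513L)
  bf <- rep(0, 100); bf[10:13] <- 1             # even run: lower median
  expect_equal(find_gap_center(mk_profile(bf)), 11L)
  # no all-black column: smoothed argmax with a warning
  bf <- 0.9 * exp(-((1:400) - 250)^2 / (2 * 30^2))
  expect_warning(ctr <- find_gap_center(mk_profile(bf)), "smoothed")
  expect_lt(abs(ctr - 250), 3)
  # max black fraction < 0.5 -> no disruption
  expect_error(find_gap_center(mk_profile(rep(0.4, 100))), "no detectable")
  # hour guard
  expect_error(find_gap_center(mk_profile(rep(1, 10), hour = 24)), "hour-0")
})

test_that("recentering shifts indices exactly and round-trips on the overlap", {
  set.seed(5)
  m <- binary_mask(random_logical_mask(30, 200))
  pr <- column_profile(m)
  # identity shift
  tc <- floor(200 / 2) + 1L
  id <- recenter(pr, center = tc, target_width = 200L)
  expect_equal(id$black_fraction, pr$black_fraction)
  # shift by +10: target column c reads source column c - shift
  sh <- recenter(pr, center = tc - 10L, target_width = 200L)
  for (c in 11:200)
    expect_identical(sh$black_fraction[c], pr$black_fraction[c - 10L])
  expect_true(all(is.na(sh$black_fraction[1:10])))
  # shift back reproduces the original on the overlap
  back <- recenter(sh, center = tc + 10L, target_width = 200L)
  ok <- !is.na(back$black_fraction)
  expect_equal(back$black_fraction[ok], pr$black_fraction[ok])
  expect_error(recenter(pr, center = 5, target_width = 0), "positive")
  expect_error(recenter(pr, center = 500), "within the profile")
})

test_that("mirror-image replicates average to a symmetric profile", {
  set.seed(9)
  px <- random_logical_mask(40, 200, 0.85)
  px[, 60:140] <- FALSE                     # planted odd-width gap (81 cols)
  px_mir <- px[, 200:1]
  pr <- column_profile(binary_mask(px))
  pr_mir <- column_profile(binary_mask(px_mir))
  c1 <- find_gap_center(pr); c2 <- find_gap_center(pr_mir)
  expect_equal(c2, 200L + 1L - c1)
  w <- 181L; tc <- floor(w / 2) + 1L
  avg <- average_profiles(list(recenter(pr, c1, w), recenter(pr_mir, c2, w)))
  # the replicates are mirror images, so the average must be symmetric about
  # the target center wherever both sides are defined
  for (k in 1:90) {
    a <- avg$mean_black_fraction[tc - k]; b <- avg$mean_black_fraction[tc + k]
    if (!is.na(a) && !is.na(b)) expect_equal(a, b, tolerance = 1e-12)
  }
})

test_that("replicate averaging tracks means, SE, counts and missingness", {
  mk <- function(bf, hour = 24) {
    structure(list(black_fraction = bf, bw_ratio = bf, height = 10L,
                   width = length(bf), condition = "c", replicate = 1L,
                   hour = hour, center = 3L), class = "column_profile")
  }
  one <- average_profiles(list(mk(c(0.2, 0.4, NA))))
  expect_equal(one$mean_black_fraction, c(0.2, 0.4, NA))
  expect_equal(one$se_black_fraction[1:2], c(0, 0))
  expect_equal(one$n_replicates, c(1L, 1L, 0L))
  two <- average_profiles(list(mk(c(0.2, 0.4, NA)), mk(c(0.4, 0.8, 0.6))))
  expect_equal(two$mean_black_fraction[1:2], c(0.3, 0.6))
  # missing columns are excluded from the mean, not zero-filled
  expect_equal(two$mean_black_fraction[3], 0.6)
  expect_equal(two$n_replicates, c(2L, 2L, 1L))
  expect_equal(two$se_black_fraction[1], sd(c(0.2, 0.4)) / sqrt(2))
  expect_error(average_profiles(list()), "at least one")
  expect_error(average_profiles(list(mk(1:3 / 4, 0), mk(1:3 / 4, 24))),
               "mix hours")
})
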