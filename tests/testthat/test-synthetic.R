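test_that("scratch simulator is deterministic and honors planted geometry", {
  p <- small_sim_params(seed = 6)
  s1 <- generate_scratch_series(p)
  s2 <- generate_scratch_series(p)
  for (h in names(s1))
    expect_identical(s1[[h]]$image$pixels, s2[[h]]$image$pixels)

  # hour 0: gap columns contain no cell pixels in truth
  t0 <- s1[["0"]]$truth
  expect_false(any(t0$cell_mask & t0$gap_mask))
  # brute-force column scan of the truth recovers planted width and center
  gap_cols <- which(apply(!t0$cell_mask, 2, all))
  expect_equal(length(gap_cols), p$gap_width_0)
  expect_equal(floor((min(gap_cols) + max(gap_cols)) / 2), p$gap_center)

  # truth consistency: occupied fraction recomputed from the emitted masks
  for (h in names(s1)) {
    tr <- s1[[h]]$truth
    expect_equal(tr$occupied_fraction_in_gap,
                 sum(tr$cell_mask & tr$gap_mask) / sum(tr$gap_mask))
    expect_equal(abs(tr$occupied_fraction_in_gap - tr$fill_fraction) <= 0.01,
                 TRUE)
  }
})

test_that("simulator validates fill schedules and feasibility", {
  expect_error(scratch_sim_params(fill_fraction = c("0" = 0.2)), "must be 0")
  expect_error(scratch_sim_params(fill_fraction = c("0" = 0, "24" = 0.8,
                                                    "48" = 0.5)),
               "non-decreasing")
  expect_error(scratch_sim_params(fill_fraction = c("24" = 0.5)), "hour 0")
  expect_error(scratch_sim_params(width = 100, height = 100,
                                  gap_center = 50, gap_width_0 = 20,
                                  cell_radius_range = c(60, 80)),
               "infeasible")
  expect_error(scratch_sim_params(cell_density = 1e6), "infeasible")
})

test_that("spot simulator plants exact centers with the requested separation", {
  g <- generate_spot_image(n_spots = 10, min_separation = 30, seed = 12)
  expect_equal(nrow(g$truth$spot_centers), 10L)
  expect_gte(g$truth$min_pairwise_distance, 30)
  # determinism
  g2 <- generate_spot_image(n_spots = 10, min_separation = 30, seed = 12)
  expect_identical(g$image$pixels, g2$image$pixels)
  # no spots: constant background plus noise, empty truth
  b <- generate_spot_image(n_spots = 0, noise_sd = 0, seed = 1)
  expect_true(all(b$image$pixels == b$image$pixels[1, 1]))
  expect_equal(nrow(b$truth$spot_centers), 0L)
  expect_error(generate_spot_image(spot_sigma = 0), "positive")
  expect_error(generate_spot_image(spot_centers = cbind(1e4, 1e4)),
               "within the canvas")
})

test_that("simulated experiments write images, truth, and a valid manifest", {
  dir <- withr::local_tempdir()
  sim <- simulate_scratch_experiment(
    dir, conditions = list(ctrl = c("0" = 0, "24" = 0.4)),
    n_replicates = 2L, base_params = small_sim_params(), seed = 2)
  man <- load_manifest(sim$manifest)
  expect_equal(nrow(man), 4L)   # 1 condition x 2 replicates x 2 hours
  expect_true(all(file.exists(man$path)))
  expect_equal(nrow(sim$truth), 4L)
  img <- load_image(man$path[1])
  expect_equal(c(img$height, img$width), c(300L, 400L))
})
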