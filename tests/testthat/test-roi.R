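test_that("sphere masks enumerate the expected voxels", {
  grid <- c(11, 11, 11)
  aff <- grid_affine(grid, 3)   # centre voxel at the world origin
  tiny <- make_sphere_mask(c(0, 0, 0), 1, grid, aff)
  expect_equal(sum(tiny$mask), 1)
  # 4 mm radius on a 3 mm grid centred on a voxel centre: the centre plus
  # its six face neighbours (distance 3) but not diagonals (4.24)
  s4 <- make_sphere_mask(c(0, 0, 0), 4, grid, aff)
  expect_equal(sum(s4$mask), 7)
  expect_error(make_sphere_mask(c(500, 0, 0), 4, grid, aff), "no voxel")
})

test_that("mask intersection is a voxelwise AND with informative errors", {
  grid <- c(8, 8, 8)
  a <- array(FALSE, grid); a[1:4, , ] <- TRUE
  b <- array(FALSE, grid); b[3:8, , ] <- TRUE
  ra <- region_mask(a, "a"); rb <- region_mask(b, "b")
  ri <- intersect_masks(ra, rb)
  expect_equal(sum(ri$mask), 2 * 64)
  expect_lte(sum(ri$mask), min(sum(a), sum(b)))
  expect_identical(intersect_masks(ra, ra)$mask, ra$mask)
  cdis <- array(FALSE, grid); cdis[5:8, , ] <- TRUE
  expect_error(intersect_masks(ra, region_mask(cdis, "c")),
               "empty intersection")
  expect_error(region_mask(array(FALSE, grid), "empty"), "empty")
})

test_that("peak selection is deterministic and respects the mask", {
  grid <- c(6, 6, 6)
  mask <- array(FALSE, grid); mask[2:5, 2:5, 2:5] <- TRUE
  rm <- region_mask(mask, "box")
  vals <- array(0, grid)
  # constant map: the first in-mask linear index wins (tie rule)
  pk <- select_peak_voxel(vals, rm)
  expect_equal(pk$index, which(mask)[1])
  # single spike
  spike <- which(mask)[20]
  vals[spike] <- 5
  expect_equal(select_peak_voxel(vals, rm)$index, spike)
  # peaks never leave the mask
  set.seed(60)
  for (i in 1:20) {
    v <- array(rnorm(216), grid)
    expect_true(select_peak_voxel(v, rm)$index %in% which(mask))
  }
  vals[] <- NA
  expect_error(select_peak_voxel(vals, rm), "NA on the whole mask")
})

test_that("the null peak behaves like the maximum of iid normals", {
  set.seed(61)
  grid <- c(6, 6, 6)
  mask <- array(FALSE, grid); mask[1:5, 1:5, 2] <- TRUE   # 25 voxels
  rm <- region_mask(mask, "sheet")
  picks <- replicate(600, {
    v <- array(rnorm(216), grid)
    select_peak_voxel(v, rm)$value
  })
  oracle <- replicate(2000, max(rnorm(25)))
  expect_equal(mean(picks), mean(oracle),
               tolerance = 3 * sd(oracle) / sqrt(600) * 5)
  expect_gt(mean(picks), 1.5)   # far above a single standard normal
})

test_that("peak and mean extraction coincide on a one-voxel mask", {
  set.seed(62)
  prof <- orthogonal_profile()
  ev <- regular_events(prof)
  des <- suppressWarnings(build_design(list(decision = ev), "3a", prof,
                                       tr = 2, n_volumes = 250))
  grid <- c(5, 5, 5)
  mask_all <- array(TRUE, grid)
  fits <- lapply(1:3, function(i) {
    Y <- matrix(rnorm(250 * 125), 250)
    fit_first_level(Y, des, mask = mask_all, affine = grid_affine(grid))
  })
  m1 <- array(FALSE, grid); m1[3, 3, 3] <- TRUE
  rm1 <- region_mask(m1, "one")
  pk <- extract_roi_signal(fits, rm1, "peak",
                           selection_contrast = c(decision_health = 1),
                           test_contrasts = list(h = c(decision_health = 1)))
  mn <- extract_roi_signal(fits, rm1, "mean",
                           test_contrasts = list(h = c(decision_health = 1)))
  expect_equal(pk$value, mn$value, tolerance = 1e-12)
})

test_that("selecting on the tested contrast inflates the extracted effect", {
  set.seed(63)
  prof <- orthogonal_profile()
  ev <- regular_events(prof)
  des <- suppressWarnings(build_design(list(decision = ev), "3a", prof,
                                       tr = 2, n_volumes = 250))
  grid <- c(5, 5, 5)
  mask_all <- array(TRUE, grid)
  rm_all <- region_mask(mask_all, "all")
  # homogeneous true signal + noise: the peak picks favourable noise
  amp <- 0.3
  fits <- lapply(1:10, function(i) {
    Y <- matrix(rep(des$X[, "decision_health"] * amp, 125), 250) +
      matrix(rnorm(250 * 125, 0, 2), 250)
    fit_first_level(Y, des, mask = mask_all, affine = grid_affine(grid))
  })
  pk <- extract_roi_signal(fits, rm_all, "peak",
                           selection_contrast = c(decision_health = 1),
                           test_contrasts = list(h = c(decision_health = 1)))
  mn <- extract_roi_signal(fits, rm_all, "mean",
                           test_contrasts = list(h = c(decision_health = 1)))
  expect_gt(mean(pk$value), mean(mn$value))
  expect_equal(mean(mn$value), amp, tolerance = 0.5)
})

test_that("selection bias experiment validates inputs and degenerate masks", {
  cfg <- sim_config(n_stimuli = 20, n_volumes_per_run = 170)
  expect_error(selection_bias_experiment(cfg, 10, n_sim = 1), "n_sim")
  set.seed(64)
  r1 <- selection_bias_experiment(cfg, mask = 1, n_sim = 30,
                                  n_subjects = 8)
  # a one-voxel mask makes both strategies the same test
  expect_equal(r1$rejection_rate_peak, r1$rejection_rate_mean)
  expect_equal(r1$mean_effect_peak, r1$mean_effect_mean)
})

test_that("spurious peak effects grow with mask size on null data", {
  set.seed(65)
  cfg <- sim_config(n_stimuli = 20, n_volumes_per_run = 170)
  eff <- vapply(c(1, 10, 100), function(m)
    selection_bias_experiment(cfg, mask = m, n_sim = 40,
                              n_subjects = 8)$mean_effect_peak, 0)
  expect_true(all(diff(eff) > 0))
})
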