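test_that("deconvolution inverts convolution on smooth signals", {
  tt <- 1:343
  x <- sin(2 * pi * tt * 2 / 343) + 0.5 * cos(2 * pi * tt * 5 / 343)
  kern <- canonical_hrf(seq(0, 32, 2)) * 2
  y <- as.numeric(stats::filter(c(rep(0, length(kern) - 1), x), kern,
                                sides = 1))[length(kern) + tt - 1]
  xd <- deconvolve_neural(y, tr = 2)
  expect_lt(sqrt(sum((xd - x)^2) / sum(x^2)), 0.05)
})

test_that("deconvolution maps zero to zero and bounds noise amplification", {
  z <- deconvolve_neural(rep(0, 200), tr = 2)
  expect_equal(as.numeric(z), rep(0, 200))
  set.seed(70)
  y <- rnorm(200)
  xd <- deconvolve_neural(y, tr = 2, lambda = 1)
  # ridge operator norm: ||x|| <= ||y|| * max_i d_i / (d_i^2 + lambda)
  sv <- scfmri:::.deconv_cache[["n200_tr2"]]
  bound <- max(sv$d / (sv$d^2 + 1)) * sqrt(sum(y^2))
  expect_lte(sqrt(sum(xd^2)), bound + 1e-8)
  expect_error(deconvolve_neural(c(1, NA, 3)), "non-finite")
})

test_that("round-trip error shrinks as noise vanishes", {
  set.seed(71)
  tt <- 1:200
  x <- sin(2 * pi * tt * 3 / 200)
  kern <- canonical_hrf(seq(0, 32, 2)) * 2
  y0 <- as.numeric(stats::filter(c(rep(0, length(kern) - 1), x), kern,
                                 sides = 1))[length(kern) + tt - 1]
  err <- vapply(c(0.5, 0.1, 0), function(s) {
    y <- y0 + rnorm(200, 0, s)
    xd <- deconvolve_neural(y, tr = 2)
    sqrt(mean((xd - x)^2))
  }, 0)
  expect_true(all(diff(err) < 0))
})

test_that("seed extraction localizes, averages and cleans the series", {
  set.seed(72)
  cfg <- sim_config(grid_shape = c(12, 12, 12), n_stimuli = 30,
                    n_volumes_per_run = 250)
  labels <- region_labels(cfg$grid_shape)
  st <- simulate_stimuli(cfg)
  lv <- attr(labels, "levels")
  search <- region_mask(array(as.integer(labels) %in%
                                match(c("dlpfc", "white_matter"), lv),
                              cfg$grid_shape), "dlpfc_or_wm",
                        affine = grid_affine(cfg$grid_shape))
  s <- simulate_subject_run(cfg, st, "SC", "decision", labels,
                            voxels = seq_len(prod(cfg$grid_shape)))
  bold4d <- aperm(array(s$bold, c(250, 12, 12, 12)), c(2, 3, 4, 1))
  seed <- extract_seed(bold4d, s$events, s$profile, s$motion, search, cfg)
  # the strongest unhealthy response lies in dlPFC (the only searched
  # region with an unhealthy-food amplitude; white matter is null)
  lab_at_peak <- labels[seed$peak$index]
  expect_equal(lv[lab_at_peak], "dlpfc")
  dl_mask <- search
  # motion projection removed: residual series is orthogonal to motion
  expect_lt(max(abs(crossprod(cbind(1, s$motion), seed$series))), 1e-6)
  # a 1 mm sphere holds a single voxel: series = that voxel minus the
  # motion projection
  seed1 <- extract_seed(bold4d, s$events, s$profile, s$motion, dl_mask,
                        cfg, sphere_radius_mm = 1)
  expect_equal(sum(seed1$sphere$mask), 1)
  vox_series <- bold4d[seed1$peak$ijk[1] + 1, seed1$peak$ijk[2] + 1,
                       seed1$peak$ijk[3] + 1, ]
  Z <- cbind(1, s$motion)
  expect_equal(seed1$series,
               as.numeric(vox_series - Z %*% qr.coef(qr(Z), vox_series)),
               tolerance = 1e-10)
})

test_that("PPI interaction is invariant to seed offsets and flags degeneracy", {
  set.seed(73)
  cfg <- sim_config(n_stimuli = 30, n_volumes_per_run = 250)
  st <- simulate_stimuli(cfg)
  prof <- simulate_subject(cfg, st, "SC")
  tm <- simulate_timing(30, cfg)
  ev <- scfmri:::make_events("decision", prof, tm, sample(30))
  motion <- simulate_motion(250)
  Y <- matrix(rnorm(250 * 20), 250)
  ser <- as.numeric(stats::filter(rnorm(250), 0.5, method = "recursive"))
  seed <- list(series = ser, neural = deconvolve_neural(ser, tr = 2))
  p1 <- suppressWarnings(run_ppi(Y, seed, ev, prof, motion, cfg))
  seed2 <- list(series = ser + 5, neural = seed$neural + 5)
  p2 <- suppressWarnings(run_ppi(Y, seed2, ev, prof, motion, cfg))
  expect_equal(p1$beta, p2$beta, tolerance = 1e-6)
  # all-neutral health ratings leave no psychological contrast
  prof0 <- prof; prof0$health[] <- 0L
  expect_error(run_ppi(Y, seed, ev, prof0, motion, cfg), "constant")
})

test_that("generative coupling modulation is recovered with its sign", {
  set.seed(74)
  cfg <- sim_config(grid_shape = c(12, 12, 12), n_stimuli = 30,
                    n_volumes_per_run = 250, ppi_coupling = 0.8,
                    noise_sd = 0.5)
  labels <- region_labels(cfg$grid_shape)
  lab_vec <- as.integer(labels)
  lv <- attr(labels, "levels")
  vox <- which(lab_vec %in% match(c("dlpfc", "ifg"), lv))
  ifg_cols <- which(lab_vec[vox] == match("ifg", lv))
  st <- simulate_stimuli(cfg)
  dl_mask <- region_mask_from_labels(labels, "dlpfc",
                                     grid_affine(cfg$grid_shape))
  grid_mask <- array(lab_vec %in% match(c("dlpfc", "ifg"), lv),
                     cfg$grid_shape)
  betas <- vapply(1:6, function(i) {
    s <- simulate_subject_run(cfg, st, "SC", "decision", labels, vox,
                              with_coupling = TRUE)
    seed <- extract_seed(s$bold, s$events, s$profile, s$motion, dl_mask,
                         cfg, grid_mask = grid_mask)
    seed$neural <- deconvolve_neural(seed, tr = cfg$tr)
    pp <- run_ppi(s$bold[, ifg_cols], seed, s$events, s$profile, s$motion,
                  cfg)
    mean(pp$beta)
  }, 0)
  tt <- t.test(betas)
  expect_gt(mean(betas), 0)
  expect_lt(tt$p.value, 0.05)
})
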