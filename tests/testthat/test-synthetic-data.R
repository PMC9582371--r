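test_that("stimulus simulation reproduces the target rating statistics", {
  set.seed(20)
  cfg <- sim_config(n_stimuli = 20000)
  st <- simulate_stimuli(cfg)
  h <- discretize_rating(st$h_latent)
  t <- discretize_rating(st$t_latent)
  expect_gt(mean(h), -0.45); expect_lt(mean(h), -0.25)
  expect_gt(sd(h), 1.30);    expect_lt(sd(h), 1.52)
  expect_gt(mean(t), 0.47);  expect_lt(mean(t), 0.67)
  expect_gt(sd(t), 0.98);    expect_lt(sd(t), 1.22)
  expect_lt(abs(cor(st$h_latent, st$t_latent)), 0.03)
})

test_that("stimulus simulation honours the correlation parameter and seed", {
  set.seed(21)
  cfg <- sim_config(n_stimuli = 5000, stim_corr = 0.6)
  st <- simulate_stimuli(cfg)
  expect_gt(cor(st$h_latent, st$t_latent), 0.5)
  expect_error(sim_config(stim_corr = 1), "stim_corr")
  set.seed(99); a <- simulate_stimuli(sim_config())
  set.seed(99); b <- simulate_stimuli(sim_config())
  expect_identical(a, b)
})

test_that("degenerate decision weights give sign-deterministic choices", {
  set.seed(22)
  cfg <- quiet_config(w_health_sc = 1, w_taste_sc = 0)
  st <- simulate_stimuli(cfg)
  p <- simulate_subject(cfg, st, "SC")
  nz <- p$health != 0
  expect_identical(sign(p$decision[nz]), sign(p$health[nz]))
})

test_that("noise-free SC-truth subjects close the loop with the classifier", {
  set.seed(23)
  cfg <- quiet_config()
  st <- simulate_stimuli(cfg)
  for (i in 1:20) {
    p <- simulate_subject(cfg, st, "SC")
    expect_equal(classify_participant(p, "three_criteria")$label, "SC")
    expect_equal(classify_participant(p, "one_criterion")$label, "SC")
  }
})

test_that("SC-truth subjects say yes to liked-unhealthy items less often", {
  set.seed(24)
  cfg <- sim_config()
  st <- simulate_stimuli(cfg)
  yes_lu <- function(true_class) {
    mean(vapply(1:15, function(i) {
      p <- simulate_subject(cfg, st, true_class)
      cc <- categorize_trials(p)
      sel <- cc$liked & cc$unhealthy & !is.na(p$decision)
      mean(p$decision[sel] > 0)
    }, 0), na.rm = TRUE)
  }
  expect_lt(yes_lu("SC") + 0.2, yes_lu("NSC"))
})

test_that("trial timing respects the task structure", {
  set.seed(25)
  cfg <- sim_config(n_volumes_per_run = 200000)
  tm <- simulate_timing(10000, cfg)
  expect_true(all(diff(tm$onset) > 0))
  expect_true(all(tm$rt > 0 & tm$rt <= 4))
  expect_true(all(tm$iti >= 4 & tm$iti <= 15))
  expect_equal(mean(tm$iti), 9.5, tolerance = 0.1)  # mean of U(4, 15)
  one <- simulate_timing(1, sim_config(), run_start = 12)
  expect_equal(one$onset, 12)
  expect_error(simulate_timing(60, sim_config(n_volumes_per_run = 100)),
               "trial [0-9]+ .*exceeds the run length")
})

test_that("null BOLD has the configured noise structure", {
  set.seed(26)
  cfg <- sim_config(grid_shape = c(8, 8, 8), drift_sd = 0,
                    effect_size_map = data.frame(
                      region = "vmpfc", regressor = "decision_gv",
                      amp_sc = 0, amp_nsc = 0))
  labels <- region_labels(cfg$grid_shape)
  st <- simulate_stimuli(cfg)
  prof <- simulate_subject(cfg, st, "SC")
  tm <- simulate_timing(cfg$n_stimuli, cfg)
  ev <- scfmri:::make_events("decision", prof, tm, sample(cfg$n_stimuli))
  td <- scfmri:::truth_design(ev, prof, cfg)
  run <- simulate_bold(td, labels, cfg, "SC", voxels = 1:200)
  v <- apply(run$data, 2, var)
  expect_equal(mean(v), 1, tolerance = 0.05)        # noise_sd^2
  # rho = 0 leaves no lag-1 autocorrelation
  cfg0 <- sim_config(grid_shape = c(8, 8, 8), ar1_rho = 0, drift_sd = 0,
                     effect_size_map = cfg$effect_size_map)
  run0 <- simulate_bold(td, labels, cfg0, "SC", voxels = 1:200)
  ac <- apply(run0$data, 2, function(x) cor(x[-1], x[-length(x)]))
  expect_lt(abs(mean(ac)), 0.02)
  # unknown region label in the amplitude map errors informatively
  cfg_bad <- cfg
  cfg_bad$effect_size_map$region <- "thalamus"
  expect_error(simulate_bold(td, labels, cfg_bad, "SC", voxels = 1:10),
               "unknown region label.*thalamus")
})

test_that("first-level GLM recovers a known goal-value amplitude", {
  set.seed(27)
  amp <- 0.6
  cfg <- sim_config(
    grid_shape = c(10, 10, 10), rating_noise_sd = 0.2,
    effect_size_map = data.frame(region = "vmpfc",
                                 regressor = "decision_gv",
                                 amp_sc = amp, amp_nsc = amp))
  labels <- region_labels(cfg$grid_shape)
  vox <- which(as.integer(labels) == 2L)   # vmpfc
  st <- simulate_stimuli(cfg)
  betas <- vapply(1:12, function(i) {
    s <- simulate_subject_run(cfg, st, "SC", "decision", labels, vox)
    des <- suppressWarnings(build_design(
      list(decision = s$events), "1", s$profile, motion = list(s$motion),
      tr = cfg$tr, n_volumes = cfg$n_volumes_per_run))
    fit <- fit_first_level(s$bold, des)
    mean(contrast_map(fit, c(decision_gv = 1))$effect)
  }, 0)
  se <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - amp), 3 * se + 0.02)
})

test_that("white-matter voxels carry no task effect by construction", {
  cfg <- sim_config()
  amp <- cfg$effect_size_map
  expect_true(all(amp[amp$region == "white_matter", c("amp_sc", "amp_nsc")]
                  == 0))
  expect_error(sim_config(effect_size_map = data.frame(
    region = "white_matter", regressor = "decision_gv",
    amp_sc = 0.5, amp_nsc = 0)), "white_matter")
})
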