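test_that("canonical HRF has the expected shape", {
  tg <- seq(0, 40, by = 0.1)
  h <- canonical_hrf(tg)
  expect_equal(h[1], 0)
  expect_true(all(h[tg > 32] == 0))
  expect_equal(max(h), 1)
  # mode of the positive gamma component (shape 6, rate 1) is at t = 5;
  # the undershoot shifts the peak only slightly
  expect_lt(abs(tg[which.max(h)] - 5), 0.3)
  expect_error(canonical_hrf(c(0, 1, 3)), "uniformly spaced")
})

test_that("orthogonalization is a sequential projection", {
  set.seed(30)
  n <- 100
  onset <- as.numeric(rep(c(0, 1), length.out = n))
  m1 <- rnorm(n); m2 <- rnorm(n)
  out <- orthogonalize_modulators(cbind(m1, m2), against = cbind(onset))
  expect_lt(abs(sum(out[, 1] * onset)), 1e-10)
  expect_lt(abs(sum(out[, 2] * out[, 1])), 1e-10)
  expect_lt(abs(sum(out[, 2] * onset)), 1e-10)
  # identical modulators: the second is fully absorbed
  out2 <- orthogonalize_modulators(cbind(m1, m1), against = cbind(onset))
  expect_lt(max(abs(out2[, 2])), 1e-10)
  # exactly orthogonal inputs are untouched
  q <- qr.Q(qr(matrix(rnorm(3 * n), n)))
  out3 <- orthogonalize_modulators(q[, 2:3], against = q[, 1, drop = FALSE])
  expect_equal(out3, q[, 2:3], tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(orthogonalize_modulators(cbind(rep(0, n))), "zero-norm")
})

test_that("a single boxcar column equals the convolved pulse", {
  prof <- make_profile(0, 0, 1)
  ev <- data.frame(onset = 16, duration = 2, trial_type = "decision",
                   stimulus_id = "s01", response = 1)
  des <- suppressWarnings(build_design(
    list(decision = ev), "2", prof, tr = 2, n_volumes = 60,
    hp_cutoff = Inf))
  # manual construction on the same microtime grid
  dt <- 2 / 16
  box <- numeric(60 * 16)
  box[(16 / dt + 1):(18 / dt)] <- 1
  kern <- canonical_hrf(seq(0, 32, by = dt))
  manual <- (stats::convolve(c(box, rep(0, length(kern))),
                             rev(kern), type = "open") * dt)[
    seq(1, by = 1, length.out = length(box))]
  samp <- (seq_len(60) - 1) * 16 + 8
  expect_equal(unname(des$X[, "yes"]), manual[samp], tolerance = 1e-8)
})

test_that("GLM1 design has the documented regressor complement", {
  set.seed(31)
  cfg <- sim_config(missing_prob = 0)
  st <- simulate_stimuli(cfg)
  prof <- simulate_subject(cfg, st, "SC")
  prof$decision[1] <- NA   # force a missing-rating trial in every run
  evs <- list(); mots <- list()
  for (b in c("health", "taste", "decision")) {
    tm <- simulate_timing(cfg$n_stimuli, cfg)
    evs[[b]] <- scfmri:::make_events(b, prof, tm, sample(cfg$n_stimuli))
    mots[[b]] <- simulate_motion(cfg$n_volumes_per_run)
  }
  des <- build_design(evs, "1", prof, motion = mots, tr = cfg$tr,
                      n_volumes = cfg$n_volumes_per_run)
  k <- table(des$cols$kind)
  expect_equal(unname(k["boxcar"]), 4L)       # 3 blocks + missing
  expect_equal(unname(k["parametric"]), 3L)   # goal value per block
  expect_equal(unname(k["constant"]), 3L)     # one per run
  expect_equal(sum(des$cols$condition == "motion"), 6L)
  expect_true("missing_ratings" %in% des$cols$name)
  expect_equal(nrow(des$X), 3 * cfg$n_volumes_per_run)
})

test_that("designs are bit-for-bit reproducible from their inputs", {
  set.seed(32)
  cfg <- sim_config()
  st <- simulate_stimuli(cfg)
  prof <- simulate_subject(cfg, st, "NSC")
  tm <- simulate_timing(cfg$n_stimuli, cfg)
  ev <- scfmri:::make_events("decision", prof, tm, seq_len(cfg$n_stimuli))
  d1 <- suppressWarnings(build_design(list(decision = ev), "4", prof,
                                      tr = 2, n_volumes = 343))
  d2 <- suppressWarnings(build_design(list(decision = ev), "4", prof,
                                      tr = 2, n_volumes = 343))
  expect_identical(d1$X, d2$X)
})

test_that("zero-trial conditions are dropped with a warning and recorded", {
  prof <- make_profile(health = c(-2, -1, -2, -1), taste = c(2, 1, 2, 1),
                       decision = c(2, 2, 1, 1))   # only failures
  ev <- regular_events(prof)
  expect_warning(
    des <- build_design(list(decision = ev), "4", prof, tr = 2,
                        n_volumes = 120),
    "zero trials")
  expect_false("sc_success" %in% des$cols$name)
  expect_true(any(grepl("sc_success", des$dropped)))
})

test_that("overlong trials are rejected with the trial named", {
  prof <- make_profile(1, 1, 1)
  ev <- data.frame(onset = 130, duration = 2, trial_type = "decision",
                   stimulus_id = "s01", response = 1)
  expect_error(suppressWarnings(
    build_design(list(decision = ev), "2", prof, tr = 2, n_volumes = 60)),
    "trial 1 .*ends after the run")
})

test_that("modulator order is irrelevant when modulators are orthogonal", {
  set.seed(33)
  prof <- orthogonal_profile()
  ev <- regular_events(prof)
  d3a <- suppressWarnings(build_design(list(decision = ev), "3a", prof,
                                       tr = 2, n_volumes = 250))
  d3b <- suppressWarnings(build_design(list(decision = ev), "3b", prof,
                                       tr = 2, n_volumes = 250))
  Y <- matrix(rnorm(250 * 40), 250)
  fa <- fit_first_level(Y, d3a)
  fb <- fit_first_level(Y, d3b)
  for (nm in c("decision_health", "decision_taste"))
    expect_lt(max(abs(fa$betas[nm, ] - fb$betas[nm, ])), 1e-6)
})

test_that("orthogonalization leaves the total model fit unchanged", {
  set.seed(34)
  n <- 60
  prof <- make_profile(sample(-2:2, n, TRUE), sample(-2:2, n, TRUE),
                       sample(-2:2, n, TRUE))
  ev <- regular_events(prof, spacing = 12, rt = 2)
  d3a <- suppressWarnings(build_design(list(decision = ev), "3a", prof,
                                       tr = 2, n_volumes = 370))
  d3b <- suppressWarnings(build_design(list(decision = ev), "3b", prof,
                                       tr = 2, n_volumes = 370))
  y <- rnorm(370)
  rss <- function(d) sum(qr.resid(qr(d$X), y)^2)
  expect_equal(rss(d3a), rss(d3b), tolerance = 1e-10)
})
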