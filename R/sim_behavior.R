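#' Discretize a latent rating to the 5-point -2..+2 scale
#'
#' Fixed symmetric cut-points at -1.5, -0.5, +0.5, +1.5 on the latent
#' scale, clamping beyond the extremes.
#'
#' @param x numeric latent values.
#' @return integer ratings in -2..+2.
#' @export
discretize_rating <- function(x) {
  as.integer(pmax(-2, pmin(2, floor(x + 0.5))))
}

#' Simulate latent stimulus attributes
#'
#' Draws per-stimulus latent healthiness H* (a junk/healthy two-component
#' normal mixture giving the wide, mildly negative health distribution of a
#' snack-food stimulus set) and tastiness T* (mildly positive normal),
#' optionally correlated through `stim_corr`. After discretization the
#' sample statistics approximate a mean health rating near -0.35 (SD 1.4)
#' and mean taste rating near 0.57 (SD 1.1).
#'
#' @param config a [sim_config()].
#' @return data.frame with `stimulus_id`, `h_latent`, `t_latent`.
#' @export
simulate_stimuli <- function(config) {
  n <- config$n_stimuli
  stopifnot(n >= 2)
  rho <- config$stim_corr
  if (abs(rho) >= 1) stop("stim_corr must lie strictly inside (-1, 1)")
  junk <- runif(n) < 0.56
  h <- ifelse(junk, rnorm(n, -1.5, 0.5), rnorm(n, 1.15, 0.5))
  z <- rnorm(n)
  hz <- as.numeric(scale(h))
  t <- 0.63 + 1.2 * (rho * hz + sqrt(1 - rho^2) * z)
  data.frame(stimulus_id = sprintf("stim%02d", seq_len(n)),
             h_latent = h, t_latent = t, stringsAsFactors = FALSE)
}

#' Simulate one subject's ratings and decisions
#'
#' Ratings are the latent stimulus attributes plus subject-level normal
#' noise, discretized to -2..+2. Decisions come from an ordered-choice
#' model on the utility u = w_h * H + w_t * T + e (H, T the subject's own
#' discretized ratings; e logistic with scale `decision_noise_sd`), mapped
#' through the same fixed cut-points; with all noise at zero the mapping is
#' deterministic. Each response is independently missing with probability
#' `missing_prob`.
#'
#' @param config a [sim_config()].
#' @param stimuli output of [simulate_stimuli()].
#' @param true_class `"SC"` or `"NSC"` (selects the true weight pair).
#' @return data.frame of class `subject_profile` with `stimulus_id`,
#'   `health`, `taste`, `decision` and attributes `true_class`, `w_health`,
#'   `w_taste`.
#' @export
simulate_subject <- function(config, stimuli, true_class = c("SC", "NSC")) {
  true_class <- match.arg(true_class)
  w_h <- if (true_class == "SC") config$w_health_sc else config$w_health_nsc
  w_t <- if (true_class == "SC") config$w_taste_sc else config$w_taste_nsc
  stopifnot(is.finite(w_h), is.finite(w_t))
  n <- nrow(stimuli)
  rate <- function(lat) {
    discretize_rating(lat + if (config$rating_noise_sd > 0)
      rnorm(n, 0, config$rating_noise_sd) else 0)
  }
  h <- rate(stimuli$h_latent)
  t <- rate(stimuli$t_latent)
  eps <- if (config$decision_noise_sd > 0)
    rlogis(n, 0, config$decision_noise_sd) else 0
  u <- w_h * h + w_t * t + eps
  d <- discretize_rating(u)
  drop <- function(x) replace(x, runif(n) < config$missing_prob, NA)
  if (config$missing_prob > 0) {
    h <- drop(h); t <- drop(t); d <- drop(d)
  }
  out <- data.frame(stimulus_id = stimuli$stimulus_id, health = h,
                    taste = t, decision = d, stringsAsFactors = FALSE)
  attr(out, "true_class") <- true_class
  attr(out, "w_health") <- w_h
  attr(out, "w_taste") <- w_t
  class(out) <- c("subject_profile", "data.frame")
  out
}

#' Simulate trial timing for one run
#'
#' Onsets are strictly increasing: each trial shows the stimulus for at
#' most 4 s (the boxcar lasts the reaction time), followed by 0.5 s of
#' feedback and an inter-trial interval uniform on 4-15 s. Reaction times
#' are truncated log-normal on (0, 4]. Errors if a trial would end after
#' the run.
#'
#' @param n_trials number of trials (>= 1).
#' @param config a [sim_config()].
#' @param run_start onset of the first trial, seconds.
#' @return data.frame with `onset`, `rt`, `feedback_onset`, `iti`.
#' @export
simulate_timing <- function(n_trials, config, run_start = 10) {
  stopifnot(n_trials >= 1)
  rt <- rlnorm(n_trials, meanlog = log(1.2), sdlog = 0.4)
  over <- rt > 4
  while (any(over)) {
    rt[over] <- rlnorm(sum(over), meanlog = log(1.2), sdlog = 0.4)
    over <- rt > 4
  }
  iti <- runif(n_trials, 4, 15)
  onset <- numeric(n_trials)
  onset[1] <- run_start
  if (n_trials > 1)
    onset[2:n_trials] <- run_start +
      cumsum(rt + 0.5 + iti)[seq_len(n_trials - 1)]
  run_len <- config$n_volumes_per_run * config$tr
  if (any(onset + 4 > run_len)) {
    bad <- which(onset + 4 > run_len)[1]
    stop(sprintf(
      "trial %d (onset %.1f s) exceeds the run length of %.0f s", bad,
      onset[bad], run_len))
  }
  data.frame(onset = onset, rt = rt, feedback_onset = onset + rt, iti = iti)
}

# assemble a BIDS-style events table for one run/block
make_events <- function(block, profile, timing, stimulus_order) {
  resp <- switch(block, health = profile$health, taste = profile$taste,
                 decision = profile$decision)
  resp <- resp[stimulus_order]
  dur <- ifelse(is.na(resp), 4, timing$rt)
  data.frame(onset = timing$onset, duration = dur, trial_type = block,
             stimulus_id = profile$stimulus_id[stimulus_order],
             response = resp, stringsAsFactors = FALSE)
}
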