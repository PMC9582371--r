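#' Peak-voxel selection bias on a null region
#'
#' Monte-Carlo quantification of circularity: on data with zero true
#' effect everywhere in the mask (the white-matter guarantee of the
#' simulator), select each subject's peak voxel on the
#' successful-minus-unsuccessful self-control contrast and run a paired t
#' test of the successful vs. unsuccessful betas at those peaks; compare
#' with the same paired test on mask-mean betas. The mean strategy is
#' calibrated (rejection rate near alpha); the peak strategy tests the
#' maximum of many noisy differences at a threshold meant for one, and
#' rejects far above alpha.
#'
#' A cohort of `n_subjects` decision-run designs (random behaviour and
#' timing per subject) is drawn once; each simulation then draws fresh
#' AR(1) noise for every voxel, so all "effects" are analysis artifacts.
#'
#' @param config a [sim_config()].
#' @param mask a [region_mask()] (canonically the white-matter label), or
#'   an integer mask size (that many arbitrary null voxels).
#' @param n_sim number of simulations (>= 2).
#' @param n_subjects cohort size per simulation.
#' @param alpha test level (.05).
#' @return list with `rejection_rate_peak`, `rejection_rate_mean`,
#'   `mean_effect_peak`, `mean_effect_mean`, `mask_size`, `n_sim`,
#'   `alpha`.
#' @export
selection_bias_experiment <- function(config, mask, n_sim = 1000,
                                      n_subjects = 20, alpha = 0.05) {
  if (n_sim < 2) stop("n_sim must be at least 2")
  v <- if (inherits(mask, "region_mask")) sum(mask$mask) else as.integer(mask)
  stopifnot(v >= 1)
  stimuli <- simulate_stimuli(config)
  n <- config$n_volumes_per_run
  # per-subject extraction rows: contrast beta = row %*% y
  rows_succ <- list(); rows_fail <- list()
  for (s in seq_len(n_subjects)) {
    repeat {
      profile <- simulate_subject(config, stimuli,
                                  if (runif(1) < 0.5) "SC" else "NSC")
      timing <- simulate_timing(config$n_stimuli, config)
      ev <- make_events("decision", profile, timing, sample(config$n_stimuli))
      des <- suppressWarnings(build_design(
        ev, "4", profile, motion = NULL, tr = config$tr, n_volumes = n))
      if (all(c("sc_success", "sc_failure") %in% des$cols$name)) break
    }
    Xp <- solve(crossprod(des$X), t(des$X))
    rows_succ[[s]] <- Xp[match("sc_success", colnames(des$X)), ]
    rows_fail[[s]] <- Xp[match("sc_failure", colnames(des$X)), ]
  }
  Rs <- do.call(rbind, rows_succ)   # n_subjects x n
  Rf <- do.call(rbind, rows_fail)
  crit <- qt(1 - alpha / 2, n_subjects - 1)
  rej_peak <- rej_mean <- logical(n_sim)
  eff_peak <- eff_mean <- numeric(n_sim)
  for (it in seq_len(n_sim)) {
    d_peak <- numeric(n_subjects); d_mean <- numeric(n_subjects)
    for (s in seq_len(n_subjects)) {
      Y <- ar1_noise(n, v, config$ar1_rho, config$noise_sd)
      bs <- as.numeric(Rs[s, ] %*% Y)
      bf <- as.numeric(Rf[s, ] %*% Y)
      diff <- bs - bf
      pk <- which.max(diff)
      d_peak[s] <- diff[pk]
      d_mean[s] <- mean(diff)
    }
    t_of <- function(d) mean(d) / (sd(d) / sqrt(n_subjects))
    rej_peak[it] <- abs(t_of(d_peak)) > crit
    rej_mean[it] <- abs(t_of(d_mean)) > crit
    eff_peak[it] <- mean(d_peak)
    eff_mean[it] <- mean(d_mean)
  }
  list(rejection_rate_peak = mean(rej_peak),
       rejection_rate_mean = mean(rej_mean),
       mean_effect_peak = mean(eff_peak),
       mean_effect_mean = mean(eff_mean),
       mask_size = v, n_sim = n_sim, alpha = alpha,
       n_subjects = n_subjects)
}
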