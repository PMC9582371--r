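# --- forward model for synthetic BOLD ------------------------------------

# ground-truth task regressors for one run: unorthogonalized HRF-convolved
# boxcar and modulator columns named "<block>", "<block>_gv", "_health",
# "_taste", plus (decision run) "unhealthy_food" and "sc_success"
truth_design <- function(events, profile, config) {
  block <- events$trial_type[1]
  prof <- profile[match(events$stimulus_id, profile$stimulus_id), ]
  tr <- config$tr; microtime <- 16L
  dt <- tr / microtime
  n_micro <- config$n_volumes_per_run * microtime
  samp <- (seq_len(config$n_volumes_per_run) - 1L) * microtime +
    ceiling(microtime / 2)
  on_b <- pmax(1L, pmin(n_micro, floor(events$onset / dt) + 1L))
  off_b <- pmax(on_b, pmin(n_micro,
    floor((events$onset + events$duration) / dt)))
  col_for <- function(vals) {   # trial-level value painted over its boxcar
    x <- numeric(n_micro)
    for (i in seq_along(on_b))
      if (!is.na(vals[i])) x[on_b[i]:off_b[i]] <- vals[i]
    x
  }
  center <- function(v) ifelse(is.na(v), NA, v - mean(v, na.rm = TRUE))
  cats <- categorize_trials(prof)
  cols <- list()
  cols[[block]] <- col_for(rep(1, nrow(events)))
  cols[[paste0(block, "_gv")]] <- col_for(center(prof$decision))
  cols[[paste0(block, "_health")]] <- col_for(center(prof$health))
  cols[[paste0(block, "_taste")]] <- col_for(center(prof$taste))
  if (block == "decision") {
    cols[["unhealthy_food"]] <- col_for(as.numeric(cats$unhealthy))
    cols[["healthy_food"]] <- col_for(as.numeric(cats$healthy))
    cols[["sc_success"]] <- col_for(as.numeric(
      cats$requires_self_control & !is.na(cats$self_control_success) &
        cats$self_control_success))
    cols[["sc_failure"]] <- col_for(as.numeric(
      cats$requires_self_control & !is.na(cats$self_control_success) &
        !cats$self_control_success))
  }
  Xm <- do.call(cbind, cols)
  X <- convolve_hrf(Xm, dt)[samp, , drop = FALSE]
  colnames(X) <- names(cols)
  # carry the unconvolved unhealthy indicator for the coupling component
  attr(X, "unhealthy_micro") <- if (block == "decision")
    Xm[, "unhealthy_food"] else NULL
  attr(X, "dt") <- dt
  attr(X, "samp") <- samp
  X
}

# AR(1) Gaussian noise, n x v matrix, stationary start
ar1_noise <- function(n, v, rho, sd) {
  e <- matrix(rnorm(n * v), n, v)
  if (rho > 0) {
    e <- stats::filter(e, rho, method = "recursive")
    e <- e * sqrt(1 - rho^2)
  }
  matrix(e * sd, n, v)
}

# low-frequency cosine drift below the 1/128 Hz cutoff (removable exactly
# by the high-pass DCT set), independent amplitude per voxel
cosine_drift <- function(n, tr, v, drift_sd) {
  B <- dct_basis(n, tr, cutoff = 128)
  k_use <- seq_len(min(3L, ncol(B)))
  if (length(k_use) == 0 || drift_sd == 0) return(matrix(0, n, v))
  A <- matrix(rnorm(length(k_use) * v, 0, drift_sd), length(k_use), v)
  B[, k_use, drop = FALSE] %*% A
}

#' Simulate motion parameters for one run
#'
#' Six slowly varying AR(1) excursion traces (3 translations mm, 3
#' rotations deg), each scaled to stay within +-1 unit; purely nuisance,
#' with no true coupling to the task.
#'
#' @param n_volumes volumes in the run.
#' @return n_volumes x 6 matrix.
#' @export
simulate_motion <- function(n_volumes) {
  m <- sapply(1:6, function(j) {
    x <- as.numeric(stats::filter(rnorm(n_volumes, 0, 0.05), 0.98,
                                  method = "recursive"))
    x <- x - x[1]
    pk <- max(abs(x))
    if (pk > 1) x <- x / pk
    x
  })
  colnames(m) <- c("trans_x", "trans_y", "trans_z",
                   "rot_x", "rot_y", "rot_z")
  m
}

#' Simulate one run of BOLD data
#'
#' Forward model: per voxel, signal = sum over task regressors of the
#' region's true amplitude times the HRF-convolved regressor, plus
#' low-order cosine drift (below the 1/128 Hz cutoff) and AR(1) Gaussian
#' noise. White-matter voxels carry noise and drift only. For the decision
#' run, a latent neural fluctuation in the seed region couples into the
#' target region during unhealthy-food trials with amplitude
#' `config$ppi_coupling` (the generative PPI effect).
#'
#' @param design_truth output of the internal truth design builder for this
#'   run (a matrix of convolved task regressors); tests may pass any
#'   matrix whose column names match the amplitude map's `regressor`
#'   entries.
#' @param labels integer label array from [region_labels()] (or a vector
#'   of per-voxel label codes when `voxels` is given).
#' @param config a [sim_config()].
#' @param true_class `"SC"` or `"NSC"`, selecting the amplitude column.
#' @param voxels optional integer vector of linear voxel indices: simulate
#'   only these voxels and return a time-by-voxel matrix instead of a 4D
#'   array.
#' @param with_coupling simulate the generative PPI component (decision
#'   runs only).
#' @return list with `data` (4D array, or matrix if `voxels` given),
#'   `motion` (n x 6), and `seed_neural` (latent seed fluctuation at frame
#'   times, `NULL` without coupling).
#' @export
simulate_bold <- function(design_truth, labels, config,
                          true_class = c("SC", "NSC"), voxels = NULL,
                          with_coupling = FALSE) {
  true_class <- match.arg(true_class)
  n <- nrow(design_truth)
  lv <- attr(labels, "levels")
  if (is.null(lv)) lv <- c("background", "vmpfc", "caudate", "dlpfc", "ifg",
                           "white_matter")
  lab_vec <- if (is.null(voxels)) as.integer(labels) else
    as.integer(labels)[voxels]
  v <- length(lab_vec)
  amp <- config$effect_size_map
  bad <- setdiff(unique(amp$region), lv)
  if (length(bad) > 0)
    stop(sprintf("amplitude map references unknown region label(s): %s",
                 paste(bad, collapse = ", ")))
  acol <- if (true_class == "SC") amp$amp_sc else amp$amp_nsc
  # per-region signal time courses
  sig_by_region <- matrix(0, n, length(lv))
  for (i in seq_len(nrow(amp))) {
    reg <- amp$regressor[i]
    if (!reg %in% colnames(design_truth)) next  # regressor absent this run
    r_ix <- match(amp$region[i], lv)
    sig_by_region[, r_ix] <- sig_by_region[, r_ix] +
      acol[i] * design_truth[, reg]
  }
  data <- sig_by_region[, lab_vec, drop = FALSE]
  seed_neural <- NULL
  if (with_coupling && !is.null(attr(design_truth, "unhealthy_micro")) &&
      config$ppi_coupling != 0) {
    dt <- attr(design_truth, "dt")
    samp <- attr(design_truth, "samp")
    n_micro <- length(attr(design_truth, "unhealthy_micro"))
    # smooth latent neural fluctuation shared across the seed region
    eta_frame <- as.numeric(stats::filter(rnorm(n, 0, 1), 0.7,
                                          method = "recursive"))
    eta_micro <- rep(eta_frame, each = n_micro / n)
    conv_eta <- convolve_hrf(cbind(eta_micro), dt)[samp, 1]
    inter <- eta_micro * attr(design_truth, "unhealthy_micro")
    conv_inter <- convolve_hrf(cbind(inter), dt)[samp, 1]
    seed_ix <- which(lab_vec == match(config$ppi_seed, lv))
    targ_ix <- which(lab_vec == match(config$ppi_target, lv))
    if (length(seed_ix) > 0)
      data[, seed_ix] <- data[, seed_ix] + conv_eta
    if (length(targ_ix) > 0)
      data[, targ_ix] <- data[, targ_ix] +
        config$ppi_coupling * conv_inter
    seed_neural <- eta_frame
  }
  data <- data + cosine_drift(n, config$tr, v, config$drift_sd) +
    ar1_noise(n, v, config$ar1_rho, config$noise_sd)
  motion <- simulate_motion(n)
  if (is.null(voxels)) {
    data <- array(data, c(n, config$grid_shape))
    data <- aperm(data, c(2, 3, 4, 1))
  }
  list(data = data, motion = motion, seed_neural = seed_neural)
}
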