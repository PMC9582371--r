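# cache of HRF-operator SVDs keyed by (length, TR)
.deconv_cache <- new.env(parent = emptyenv())

#' Extract a seed time series for PPI
#'
#' Fits the seed-localizer GLM (healthy-food and unhealthy-food boxcars
#' plus motion, constant and high-pass columns; decision run only), finds
#' the voxel with the strongest positive unhealthy-food response within
#' the supplied mask, averages the BOLD series over a sphere around that
#' peak (default radius 4 mm), and removes variance associated with the
#' motion regressors (and the constant) from the averaged series.
#'
#' @param bold decision-run BOLD: 4D array or time-by-voxel matrix over
#'   `grid_mask`.
#' @param events decision-run events data.frame.
#' @param profile subject rating profile.
#' @param motion n x 6 motion matrix.
#' @param mask a [region_mask()] to search for the peak.
#' @param config a [sim_config()].
#' @param grid_mask logical array mapping matrix columns to grid voxels
#'   (defaults to the full grid).
#' @param sphere_radius_mm sphere radius around the peak (4).
#' @return list of class `seed_timeseries`: `series` (motion-residualized,
#'   length n), `raw_series`, `peak` (as from [select_peak_voxel()]),
#'   `sphere` ([region_mask()]), `fit`.
#' @export
extract_seed <- function(bold, events, profile, motion, mask, config,
                         grid_mask = NULL, sphere_radius_mm = 4) {
  grid <- config$grid_shape
  if (length(dim(bold)) == 4L) {
    if (is.null(grid_mask)) grid_mask <- array(TRUE, dim(bold)[1:3])
    dm <- dim(bold)
    Y <- t(matrix(bold, prod(dm[1:3]), dm[4]))[, as.logical(grid_mask),
                                               drop = FALSE]
  } else {
    Y <- as.matrix(bold)
    if (is.null(grid_mask)) stop("matrix BOLD input needs grid_mask")
  }
  affine <- grid_affine(grid, config$voxel_size)
  des <- suppressWarnings(build_design(
    events, "ppi_seed", profile, motion = list(motion), tr = config$tr,
    n_volumes = config$n_volumes_per_run))
  fit <- fit_first_level(Y, des, mask = grid_mask, affine = affine)
  if (!"unhealthy_food" %in% rownames(fit$betas))
    stop("no unhealthy-food trials: seed localizer undefined")
  sel <- contrast_map(fit, c(unhealthy_food = 1))
  pk <- select_peak_voxel(sel$effect_map, mask)
  sphere <- make_sphere_mask(pk$mm, sphere_radius_mm, grid, affine)
  in_cols <- which(which(grid_mask) %in% which(sphere$mask & grid_mask))
  if (length(in_cols) == 0) stop("sphere contains no analysed voxels")
  raw <- rowMeans(Y[, in_cols, drop = FALSE])
  Z <- cbind(1, motion)
  series <- as.numeric(raw - Z %*% qr.coef(qr(Z), raw))
  structure(list(series = series, raw_series = raw, peak = pk,
                 sphere = sphere, fit = fit),
            class = "seed_timeseries")
}

#' Deconvolve a BOLD series to an underlying neural series
#'
#' Ridge-regularized least-squares inversion of the causal HRF convolution
#' operator at the acquisition resolution: the Toeplitz matrix H of the
#' canonical HRF sampled at TR is inverted as
#' x = argmin ||y - Hx||^2 + lambda ||x||^2, with lambda chosen by
#' generalized cross-validation over a log grid (fallback lambda = 1 when
#' GCV is degenerate).
#'
#' @param seed a `seed_timeseries` or numeric vector.
#' @param tr sampling interval, seconds.
#' @param lambda fixed ridge penalty; `NULL` (default) selects by GCV.
#' @return numeric neural series, same length; attributes `lambda`,
#'   `gcv`.
#' @export
deconvolve_neural <- function(seed, tr = 2, lambda = NULL) {
  y <- if (inherits(seed, "seed_timeseries")) seed$series else as.numeric(seed)
  if (!all(is.finite(y))) stop("seed series contains non-finite values")
  n <- length(y)
  key <- sprintf("n%d_tr%g", n, tr)
  sv <- .deconv_cache[[key]]
  if (is.null(sv)) {
    kern <- canonical_hrf(seq(0, 32, by = tr)) * tr
    H <- matrix(0, n, n)
    for (k in seq_along(kern)) {
      i <- seq(k, n)
      H[cbind(i, i - k + 1L)] <- kern[k]
    }
    sv <- svd(H)
    .deconv_cache[[key]] <- sv
  }
  d <- sv$d
  uty <- crossprod(sv$u, y)
  if (is.null(lambda)) {
    gcv <- function(l) {
      f <- d^2 / (d^2 + l)
      rss <- sum(((1 - f) * uty)^2)
      (rss / n) / (1 - sum(f) / n)^2
    }
    grid <- 10^seq(-8, 2, length.out = 60)
    scores <- vapply(grid, gcv, 0)
    lambda <- if (all(is.finite(scores))) grid[which.min(scores)] else 1
    attr_gcv <- min(scores, na.rm = TRUE)
  } else attr_gcv <- NA_real_
  x <- sv$v %*% (d / (d^2 + lambda) * uty)
  structure(as.numeric(x), lambda = lambda, gcv = attr_gcv)
}

# unhealthy/healthy psychological indicator sampled at frame times:
# +1 over unhealthy-food trial windows, -1 over healthy, 0 elsewhere;
# stimuli with neutral health rating are excluded by default
psych_indicator <- function(events, profile, tr, n_volumes,
                            include_neutral = FALSE) {
  prof <- profile[match(events$stimulus_id, profile$stimulus_id), ]
  tt <- (seq_len(n_volumes) - 0.5) * tr
  ind <- numeric(n_volumes)
  for (i in seq_len(nrow(events))) {
    h <- prof$health[i]
    if (is.na(h)) next
    sgn <- if (h < 0) 1 else if (h > 0) -1 else if (include_neutral) 0 else next
    if (sgn == 0) next
    win <- tt >= events$onset[i] & tt < events$onset[i] + events$duration[i]
    ind[win] <- sgn
  }
  ind
}

#' Run a psychophysiological-interaction regression
#'
#' Voxelwise regression of decision-run BOLD on (a) the interaction of the
#' deconvolved seed neural series with the centred unhealthy-trial
#' indicator, (b) the indicator, and (c) the seed series itself, plus
#' motion, high-pass and constant nuisance columns; (a) and (b) are
#' HRF-convolved, (c) is the observed (already hemodynamic) seed series.
#' The indicator is coded +1/2 on unhealthy-food windows and -1/2 on
#' healthy-food windows to limit main-effect collinearity. A variance
#' inflation factor of the interaction column above 30 triggers a warning.
#'
#' @param bold decision-run time-by-voxel matrix (or 4D array plus
#'   `grid_mask`).
#' @param seed a `seed_timeseries` (its motion-cleaned series is used as
#'   regressor c and its deconvolution as the neural series) or a list
#'   with `series` and `neural`.
#' @param events,profile decision-run events and rating profile (define
#'   the indicator).
#' @param motion n x 6 motion matrix.
#' @param config a [sim_config()].
#' @param grid_mask logical array for 4D input / map output.
#' @return list with `beta` (interaction beta per voxel), `t`, `se`, `df`,
#'   `vif`, `design`, and `beta_map`/`t_map` when geometry is available.
#' @export
run_ppi <- function(bold, seed, events, profile, motion, config,
                    grid_mask = NULL) {
  n <- config$n_volumes_per_run
  if (length(dim(bold)) == 4L) {
    if (is.null(grid_mask)) grid_mask <- array(TRUE, dim(bold)[1:3])
    dm <- dim(bold)
    Y <- t(matrix(bold, prod(dm[1:3]), dm[4]))[, as.logical(grid_mask),
                                               drop = FALSE]
  } else Y <- as.matrix(bold)
  series <- if (inherits(seed, "seed_timeseries")) seed$series else seed$series
  neural <- if (!is.null(seed$neural)) seed$neural
            else deconvolve_neural(seed, tr = config$tr)
  ind <- psych_indicator(events, profile, config$tr, n)
  if (sd(ind) == 0)
    stop("psychological indicator is constant; interaction undefined")
  psych <- ind / 2
  kern_conv <- function(x) {
    convolve_hrf(cbind(x), config$tr)[, 1]
  }
  a <- kern_conv(as.numeric(neural) * psych)
  b <- kern_conv(psych)
  X <- cbind(ppi_interaction = a, psych = b, seed = series, motion,
             dct_basis(n, config$tr, 128), constant = 1)
  colnames(X)[seq_len(ncol(X))[colnames(X) == ""]] <- paste0(
    "nuis", seq_len(sum(colnames(X) == "")))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("PPI design is rank deficient")
  others <- X[, -1, drop = FALSE]
  ra <- a - others %*% qr.coef(qr(others), a)
  vif <- sum((a - mean(a))^2) / sum(ra^2)
  if (vif > 30)
    warning(sprintf(
      "interaction regressor is nearly collinear with main effects (VIF %.1f)",
      vif), call. = FALSE)
  betas <- qr.coef(qx, Y)
  res <- Y - X %*% betas
  df <- n - qx$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(sigma2 * xtx_inv[1, 1])
  beta <- betas[1, ]
  out <- list(beta = beta, t = beta / se, se = se, df = df, vif = vif,
              design = X)
  if (!is.null(grid_mask)) {
    affine <- grid_affine(config$grid_shape, config$voxel_size)
    out$beta_map <- vol_map(beta, grid_mask, affine, "beta")
    out$t_map <- vol_map(beta / se, grid_mask, affine, "t")
  }
  out
}
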