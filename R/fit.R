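#' Fit a first-level GLM with AR(1) prewhitening
#'
#' Per voxel: ordinary least squares, then a single lag-1 autocorrelation
#' estimate pooled over the analysis mask from the OLS residuals
#' (run-wise, so the estimate never crosses run boundaries), a (1, -rho)
#' prewhitening transform applied to data and design, and a final
#' generalized-least-squares pass. Residual degrees of freedom are
#' n - rank(X); the high-pass discrete-cosine columns live inside the
#' design, so filtering is accounted for automatically.
#'
#' @param bold 4D array (x, y, z, time; time may span concatenated runs) or
#'   a time-by-voxel matrix of in-mask series.
#' @param design an [build_design()] result whose `X` has as many rows as
#'   `bold` has time points.
#' @param mask logical 3D array selecting analysis voxels (required for 4D
#'   input; ignored for matrix input).
#' @param affine voxel-to-world matrix carried into output maps.
#' @return object of class `first_level_fit`: `betas` (regressor x voxel),
#'   `sigma2`, `df`, `rho`, `xtx_inv`, `design`, `mask`, `affine`.
#' @export
fit_first_level <- function(bold, design, mask = NULL, affine = NULL) {
  X <- design$X
  if (length(dim(bold)) == 4L) {
    if (is.null(mask)) mask <- array(TRUE, dim(bold)[1:3])
    dm <- dim(bold)
    Y <- t(matrix(bold, prod(dm[1:3]), dm[4]))[, as.logical(mask),
                                               drop = FALSE]
  } else {
    Y <- as.matrix(bold)
  }
  if (nrow(Y) != nrow(X))
    stop(sprintf("BOLD has %d time points but design has %d rows",
                 nrow(Y), nrow(X)))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    keep <- qx$pivot[seq_len(qx$rank)]
    stop(sprintf("design is rank deficient; collinear column(s): %s",
                 paste(colnames(X)[-keep], collapse = ", ")))
  }
  beta0 <- qr.coef(qx, Y)
  resid0 <- Y - X %*% beta0
  n_per <- design$n_volumes
  runs <- design$runs
  num <- 0; den <- 0
  for (r in seq_len(runs)) {
    rows <- (r - 1L) * n_per + seq_len(n_per)
    e <- resid0[rows, , drop = FALSE]
    num <- num + sum(e[-1, ] * e[-nrow(e), ])
    den <- den + sum(e^2)
  }
  # residuals at rounding-error scale carry no autocorrelation information
  rho <- if (den > 1e-10 * max(sum(Y^2), 1)) num / den else 0
  rho <- max(min(rho, 0.99), -0.99)
  whiten <- function(M) {
    W <- M
    for (r in seq_len(runs)) {
      rows <- (r - 1L) * n_per + seq_len(n_per)
      blk <- M[rows, , drop = FALSE]
      out <- blk
      out[1, ] <- blk[1, ] * sqrt(1 - rho^2)
      out[-1, ] <- blk[-1, ] - rho * blk[-nrow(blk), , drop = FALSE]
      W[rows, ] <- out
    }
    W
  }
  Xw <- whiten(X); Yw <- whiten(Y)
  qw <- qr(Xw)
  betas <- qr.coef(qw, Yw)
  res <- Yw - Xw %*% betas
  df <- nrow(Xw) - qw$rank
  sigma2 <- colSums(res^2) / df
  xtx_inv <- solve(crossprod(Xw))
  dimnames(xtx_inv) <- list(colnames(X), colnames(X))
  rownames(betas) <- colnames(X)
  structure(list(betas = betas, sigma2 = sigma2, df = df, rho = rho,
                 xtx_inv = xtx_inv, design = design, mask = mask,
                 affine = affine),
            class = "first_level_fit")
}

#' @export
print.first_level_fit <- function(x, ...) {
  cat(sprintf("<first_level_fit GLM%s> %d voxels, df = %d, rho_hat = %.3f\n",
              x$design$glm_id, ncol(x$betas), x$df, x$rho))
  invisible(x)
}

# resolve a named contrast vector against a fit's columns
contrast_weights <- function(fit, weights) {
  p <- nrow(fit$betas)
  if (!is.null(names(weights))) {
    missing_cols <- setdiff(names(weights), rownames(fit$betas))
    if (length(missing_cols) > 0)
      stop(sprintf("contrast references absent column(s): %s%s",
                   paste(missing_cols, collapse = ", "),
                   if (length(fit$design$dropped) > 0)
                     sprintf(" (dropped: %s)",
                             paste(fit$design$dropped, collapse = ", "))
                   else ""))
    w <- numeric(p); names(w) <- rownames(fit$betas)
    w[names(weights)] <- weights
  } else {
    if (length(weights) != p)
      stop(sprintf("contrast length %d != %d regressors", length(weights), p))
    w <- weights
  }
  w
}

#' Contrast effect and t map from a first-level fit
#'
#' @param fit a [fit_first_level()] result.
#' @param weights contrast weights: named vector (resolved by regressor
#'   name; naming a dropped column is an error) or full-length numeric.
#' @return list with `effect` and `t` vectors over voxels, `se`, `df`; and
#'   `effect_map`/`t_map` as [vol_map()]s when the fit has a mask.
#' @export
contrast_map <- function(fit, weights) {
  w <- contrast_weights(fit, weights)
  effect <- as.numeric(t(w) %*% fit$betas)
  qf <- as.numeric(t(w) %*% fit$xtx_inv %*% w)
  se <- sqrt(fit$sigma2 * qf)
  tval <- effect / se
  out <- list(effect = effect, se = se, t = tval, df = fit$df, weights = w)
  if (!is.null(fit$mask) && is.array(fit$mask)) {
    out$effect_map <- vol_map(effect, fit$mask, fit$affine, "beta")
    out$t_map <- vol_map(tval, fit$mask, fit$affine, "t")
  }
  out
}
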