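#' Canonical double-gamma hemodynamic response function
#'
#' The canonical HRF used throughout the package: a positive gamma density
#' peaking near 5-6 s minus a later undershoot gamma (peak delay 6 s,
#' undershoot delay 16 s, unit dispersions, undershoot amplitude ratio 1/6),
#' truncated at 32 s and scaled to unit peak.
#'
#' @param t_grid nonnegative, uniformly spaced time grid in seconds.
#' @return numeric kernel, same length as `t_grid`.
#' @export
canonical_hrf <- function(t_grid) {
  stopifnot(is.numeric(t_grid), all(t_grid >= 0))
  if (length(t_grid) > 1) {
    dt <- diff(t_grid)
    if (max(abs(dt - dt[1])) > 1e-8) stop("t_grid must be uniformly spaced")
  }
  h <- dgamma(t_grid, shape = 6, rate = 1) -
    dgamma(t_grid, shape = 16, rate = 1) / 6
  h[t_grid > 32] <- 0
  pk <- max(h)
  if (pk > 0) h <- h / pk
  h
}

# causal convolution of each column of x (sampled at dt) with the canonical
# HRF, keeping the original length
convolve_hrf <- function(x, dt) {
  x <- as.matrix(x)
  kern <- canonical_hrf(seq(0, 32, by = dt))
  n <- nrow(x)
  nk <- length(kern)
  # zero-padded FFT convolution, truncated back to n samples
  m <- stats::nextn(n + nk - 1, 2)
  kf <- stats::fft(c(kern, rep(0, m - nk)))
  xf <- stats::mvfft(rbind(x, matrix(0, m - n, ncol(x))))
  out <- Re(stats::mvfft(xf * kf, inverse = TRUE)) / m
  out[seq_len(n), , drop = FALSE] * dt
}
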