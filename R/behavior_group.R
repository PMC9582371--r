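#' Group choice proportions, group tests and rating correlations
#'
#' For each food category (liked-healthy, liked-unhealthy, disliked-healthy,
#' disliked-unhealthy, by each subject's own ratings) computes the
#' per-subject proportion of "yes"/"strong yes" decisions, group means and
#' standard errors, and a pooled-variance two-sample t test between groups
#' (df = n1 + n2 - 2, matching the t(78)-style reporting convention).
#' Additionally correlates the per-stimulus mean health and taste ratings
#' between the two groups (Pearson, with confidence interval).
#'
#' @param profiles list of per-subject rating data.frames.
#' @param labels character vector of group labels, `"SC"`/`"NSC"`, parallel
#'   to `profiles`; other labels are ignored.
#' @return list with `proportions` (one row per category: group means, SEs,
#'   t, df, p, per-group subject counts), `rating_correlations` (one row
#'   per rating scale: r, CI, t, df, p) and `excluded` (subject x category
#'   cells with no scorable stimuli).
#' @export
group_choice_table <- function(profiles, labels) {
  stopifnot(length(profiles) == length(labels))
  sc <- which(labels == "SC"); nsc <- which(labels == "NSC")
  if (length(sc) == 0 || length(nsc) == 0)
    stop("both groups must be non-empty")
  cat_defs <- list(
    liked_healthy = function(cc) cc$liked & cc$healthy,
    liked_unhealthy = function(cc) cc$liked & cc$unhealthy,
    disliked_healthy = function(cc) cc$disliked & cc$healthy,
    disliked_unhealthy = function(cc) cc$disliked & cc$unhealthy)
  yes_prop <- function(p, f) {
    cc <- categorize_trials(p)
    sel <- f(cc) & !is.na(p$decision)
    if (!any(sel)) return(NA_real_)
    mean(p$decision[sel] > 0)
  }
  excluded <- character()
  rows <- lapply(names(cat_defs), function(cn) {
    v_sc <- vapply(profiles[sc], yes_prop, 0, f = cat_defs[[cn]])
    v_nsc <- vapply(profiles[nsc], yes_prop, 0, f = cat_defs[[cn]])
    drop <- c(sc[is.na(v_sc)], nsc[is.na(v_nsc)])
    if (length(drop) > 0)
      excluded <<- c(excluded, paste0(cn, ":subject", drop))
    v_sc <- v_sc[!is.na(v_sc)]; v_nsc <- v_nsc[!is.na(v_nsc)]
    if (length(v_sc) < 2 || length(v_nsc) < 2) {
      return(data.frame(category = cn, mean_sc = mean(v_sc),
                        se_sc = NA_real_, mean_nsc = mean(v_nsc),
                        se_nsc = NA_real_, t = NA_real_, df = NA_real_,
                        p = NA_real_, n_sc = length(v_sc),
                        n_nsc = length(v_nsc), stringsAsFactors = FALSE))
    }
    if (sd(c(v_sc, v_nsc)) == 0) {
      tt <- list(statistic = c(t = 0), parameter =
                   c(df = length(v_sc) + length(v_nsc) - 2), p.value = 1)
    } else {
      tt <- t.test(v_sc, v_nsc, var.equal = TRUE)
    }
    data.frame(category = cn, mean_sc = mean(v_sc), se_sc = sd(v_sc) /
                 sqrt(length(v_sc)), mean_nsc = mean(v_nsc),
               se_nsc = sd(v_nsc) / sqrt(length(v_nsc)),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, n_sc = length(v_sc), n_nsc = length(v_nsc),
               stringsAsFactors = FALSE)
  })
  stim_mean <- function(idx, col) {
    m <- sapply(profiles[idx], function(p) p[[col]])
    rowMeans(m, na.rm = TRUE)
  }
  cors <- lapply(c("health", "taste"), function(col) {
    a <- stim_mean(sc, col); b <- stim_mean(nsc, col)
    ct <- cor.test(a, b)
    data.frame(rating = col, r = unname(ct$estimate),
               ci_lo = ct$conf.int[1], ci_hi = ct$conf.int[2],
               t = unname(ct$statistic), df = unname(ct$parameter),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  list(proportions = do.call(rbind, rows),
       rating_correlations = do.call(rbind, cors), excluded = excluded)
}

#' Huber robust regression with sandwich standard errors
#'
#' Iteratively reweighted least squares with the Huber psi (tuning constant
#' 1.345, residual scale re-estimated each iteration by the MAD), stopping
#' when the largest coefficient change drops below 1e-8 or after 50
#' iterations (non-convergence is an error reporting the last iterate).
#' Standard errors are of the heteroscedasticity-robust sandwich type based
#' on the final IRLS weights.
#'
#' @param x numeric predictor vector or matrix (without intercept).
#' @param y numeric response.
#' @param covariates optional additional predictor matrix.
#' @return data.frame with one row per coefficient (intercept first):
#'   `estimate`, `se`, `t`, `p` (t reference with n - p df), plus
#'   attributes `iterations` and `scale`.
#' @export
robust_regression <- function(x, y, covariates = NULL) {
  X <- cbind(`(Intercept)` = 1, as.matrix(x))
  if (is.null(colnames(X)) || any(colnames(X)[-1] == ""))
    colnames(X)[-1] <- paste0("x", seq_len(ncol(X) - 1))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("z", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more observations than parameters")
  sds <- apply(X[, -1, drop = FALSE], 2, sd)
  if (any(sds == 0))
    stop(sprintf("constant predictor: %s",
                 paste(colnames(X)[-1][sds == 0], collapse = ", ")))
  k <- 1.345
  beta <- qr.coef(qr(X), y)
  for (it in seq_len(50)) {
    r <- y - X %*% beta
    s <- mad(r, center = 0)
    if (s < 1e-10) s <- sd(r) + 1e-12
    u <- as.numeric(r) / s
    w <- ifelse(abs(u) <= k, 1, k / abs(u))
    beta_new <- qr.coef(qr(X * sqrt(w)), y * sqrt(w))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < 1e-8) break
    if (it == 50)
      stop(sprintf("IRLS did not converge in 50 iterations (last max change %.3g; coefficients %s)",
                   delta, paste(signif(beta, 6), collapse = ", ")))
  }
  r <- as.numeric(y - X %*% beta)
  s <- mad(r, center = 0); if (s < 1e-10) s <- sd(r) + 1e-12
  u <- r / s
  w <- ifelse(abs(u) <= k, 1, k / abs(u))
  XtWX <- crossprod(X * sqrt(w))
  bread <- solve(XtWX)
  meat <- crossprod(X * (w * r))
  V <- bread %*% meat %*% bread * n / (n - p)
  se <- sqrt(diag(V))
  tval <- as.numeric(beta) / se
  out <- data.frame(term = colnames(X), estimate = as.numeric(beta), se = se,
                    t = tval, p = 2 * pt(-abs(tval), df = n - p),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "iterations") <- it
  attr(out, "scale") <- s
  out
}
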