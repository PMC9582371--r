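#' Categorize stimuli by liking, healthiness and self-control demand
#'
#' A trial requires self-control when the shown food is liked but unhealthy
#' (taste > 0, health < 0) or disliked but healthy (taste < 0, health > 0);
#' the neutral rating 0 belongs to neither side. Self-control succeeds when
#' a liked-unhealthy item is declined (decision < 0) or a disliked-healthy
#' item is chosen (decision > 0); a neutral decision on a self-control trial
#' counts as failure. Stimuli with a missing health or taste rating are
#' excluded from the self-control definition.
#'
#' @param profile data.frame with one row per stimulus and integer columns
#'   `health`, `taste`, `decision` on the -2..+2 scale (`NA` = missing).
#' @return data.frame of per-stimulus logical flags: `liked`, `disliked`,
#'   `healthy`, `unhealthy`, `requires_self_control`,
#'   `self_control_success` (`NA` where undefined), `neutral_decision`,
#'   `missing_any`.
#' @export
categorize_trials <- function(profile) {
  h <- profile$health; t <- profile$taste; d <- profile$decision
  liked <- !is.na(t) & t > 0
  disliked <- !is.na(t) & t < 0
  healthy <- !is.na(h) & h > 0
  unhealthy <- !is.na(h) & h < 0
  req <- (liked & unhealthy) | (disliked & healthy)
  succ <- rep(NA, length(req))
  idx <- which(req & !is.na(d))
  succ[idx] <- ifelse(liked[idx] & unhealthy[idx], d[idx] < 0, d[idx] > 0)
  data.frame(stimulus_id = profile$stimulus_id, liked = liked,
             disliked = disliked, healthy = healthy, unhealthy = unhealthy,
             requires_self_control = req, self_control_success = succ,
             neutral_decision = !is.na(d) & d == 0,
             missing_any = is.na(h) | is.na(t) | is.na(d))
}

#' Individual choice regressions of decisions on health and taste
#'
#' Ordinary least squares of the decision (goal value) rating on the health
#' and taste ratings jointly, plus the two simple regressions, over stimuli
#' with all three ratings present.
#'
#' @param profile per-stimulus ratings data.frame (see
#'   [categorize_trials()]).
#' @return list with `b_health`, `b_taste` (multiple-regression slopes),
#'   `b_health_std`, `b_taste_std` (standardized), `r2_health`, `r2_taste`
#'   (simple-regression R-squared) and `n`.
#' @export
choice_regressions <- function(profile) {
  ok <- complete.cases(profile[, c("health", "taste", "decision")])
  h <- profile$health[ok]; t <- profile$taste[ok]; d <- profile$decision[ok]
  if (length(d) < 3) stop("need at least 3 stimuli with complete ratings")
  for (nm in c("health", "taste"))
    if (sd(get(substr(nm, 1, 1))) == 0)
      stop(sprintf("constant regressor: %s rating has zero variance", nm))
  fit <- lm(d ~ h + t)
  b <- coef(fit)
  r2 <- function(x) {
    f <- lm(d ~ x); 1 - sum(resid(f)^2) / sum((d - mean(d))^2)
  }
  sd_d <- sd(d)
  list(b_health = unname(b["h"]), b_taste = unname(b["t"]),
       b_health_std = unname(b["h"]) * sd(h) / sd_d,
       b_taste_std = unname(b["t"]) * sd(t) / sd_d,
       r2_health = r2(h), r2_taste = r2(t), n = length(d))
}

#' Classify a participant as self-controller (SC) or not (NSC)
#'
#' Three-criteria mode: SC requires (1) self-control success on strictly
#' more than 50% of trials that require it, (2) a larger standardized
#' health than taste effect (in absolute value) in the multiple regression
#' of decisions on both ratings, and (3) a larger simple-regression
#' R-squared for health than for taste. NSC means none of the three holds;
#' anything else is unclassified. One-criterion mode: SC iff the success
#' rate is at least 50% (note the relaxed boundary), otherwise NSC.
#' Missing decisions are excluded from both numerator and denominator of
#' the success rate.
#'
#' @param profile per-stimulus ratings data.frame.
#' @param mode `"three_criteria"` or `"one_criterion"`.
#' @return list of class `classification_result`: `label` in
#'   `c("SC", "NSC", "unclassified")`, `criterion1_rate`,
#'   `criterion1_pass`, `criterion2_pass`, `criterion3_pass`, the
#'   regression summaries, `n_sc_trials` and `mode`.
#' @export
classify_participant <- function(profile,
                                 mode = c("three_criteria", "one_criterion")) {
  mode <- match.arg(mode)
  cats <- categorize_trials(profile)
  usable <- cats$requires_self_control & !is.na(cats$self_control_success)
  n_sc <- sum(usable)
  if (n_sc == 0) {
    return(structure(list(label = "unclassified", criterion1_rate = NA_real_,
                          criterion1_pass = NA, criterion2_pass = NA,
                          criterion3_pass = NA, regressions = NULL,
                          n_sc_trials = 0L, mode = mode,
                          diagnostic = "no usable self-control-required trials"),
                     class = "classification_result"))
  }
  rate <- mean(cats$self_control_success[usable])
  if (mode == "one_criterion") {
    label <- if (rate >= 0.5) "SC" else "NSC"
    return(structure(list(label = label, criterion1_rate = rate,
                          criterion1_pass = rate >= 0.5, criterion2_pass = NA,
                          criterion3_pass = NA, regressions = NULL,
                          n_sc_trials = n_sc, mode = mode),
                     class = "classification_result"))
  }
  reg <- choice_regressions(profile)
  c1 <- rate > 0.5
  c2 <- abs(reg$b_health_std) > abs(reg$b_taste_std)
  c3 <- reg$r2_health > reg$r2_taste
  label <- if (c1 && c2 && c3) "SC" else if (!c1 && !c2 && !c3) "NSC"
           else "unclassified"
  structure(list(label = label, criterion1_rate = rate, criterion1_pass = c1,
                 criterion2_pass = c2, criterion3_pass = c3,
                 regressions = reg, n_sc_trials = n_sc, mode = mode),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<%s> %s (criterion-1 rate %.2f over %d trials)\n", x$mode,
              x$label, x$criterion1_rate, x$n_sc_trials))
  invisible(x)
}
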