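test_that("trial categorization follows the liked/healthy definitions", {
  p <- make_profile(health = c(-2, -1, -2, 1, 0, NA),
                    taste = c(2, 1, 0, -1, 2, 1),
                    decision = c(-1, 2, -2, 1, 0, 1))
  cc <- categorize_trials(p)
  # liked-unhealthy declined -> success
  expect_true(cc$requires_self_control[1])
  expect_true(cc$self_control_success[1])
  # liked-unhealthy chosen -> failure
  expect_true(cc$requires_self_control[2])
  expect_false(cc$self_control_success[2])
  # taste-neutral stimulus never requires self-control
  expect_false(cc$requires_self_control[3])
  # disliked-healthy chosen -> success
  expect_true(cc$self_control_success[4])
  # rating 0 belongs to neither side
  expect_false(cc$liked[3] || cc$disliked[3])
  # missing health rating excluded from the definition
  expect_false(cc$requires_self_control[6])
  expect_true(cc$missing_any[6])
})

test_that("neutral decisions on self-control trials count as failures", {
  p <- make_profile(health = -2, taste = 2, decision = 0)
  cc <- categorize_trials(p)
  expect_true(cc$requires_self_control)
  expect_false(cc$self_control_success)
})

test_that("choice regressions reproduce exact and degenerate cases", {
  set.seed(1)
  h <- sample(-2:2, 30, replace = TRUE)
  t <- sample(-2:2, 30, replace = TRUE)
  p1 <- make_profile(h, t, h)            # decisions identical to health
  r1 <- choice_regressions(p1)
  expect_equal(r1$b_health, 1, tolerance = 1e-10)
  expect_equal(r1$b_taste, 0, tolerance = 1e-10)
  expect_equal(r1$r2_health, 1, tolerance = 1e-10)
  p2 <- make_profile(h, t, t)            # decisions identical to taste
  r2 <- choice_regressions(p2)
  expect_equal(r2$r2_taste, 1, tolerance = 1e-10)
  expect_equal(r2$r2_health, cor(h, t)^2, tolerance = 1e-10)
  expect_error(choice_regressions(make_profile(rep(1, 10), t[1:10], h[1:10])),
               "constant regressor: health")
  expect_error(choice_regressions(make_profile(1, 1, 1)), "at least 3")
})

test_that("choice regressions match the normal-equation oracle", {
  set.seed(2)
  for (i in 1:25) {
    n <- sample(10:50, 1)
    h <- sample(-2:2, n, replace = TRUE)
    t <- sample(-2:2, n, replace = TRUE)
    if (sd(h) == 0 || sd(t) == 0) next
    d <- rnorm(n)
    r <- choice_regressions(make_profile(h, t, round(d)))
    d2 <- round(d)
    X <- cbind(1, h, t)
    b <- solve(t(X) %*% X, t(X) %*% d2)   # textbook normal equations
    expect_equal(r$b_health, b[2], tolerance = 1e-10)
    expect_equal(r$b_taste, b[3], tolerance = 1e-10)
  }
})

test_that("classification boundary and degenerate cases behave as specified", {
  # exactly 50% success: SC under one criterion, criterion 1 fails under three
  p <- make_profile(health = c(-1, -1, 2, 2), taste = c(2, 2, 1, 0),
                    decision = c(-2, 2, 1, 1))
  cc <- categorize_trials(p)
  expect_equal(sum(cc$requires_self_control), 2)
  one <- classify_participant(p, "one_criterion")
  expect_equal(one$criterion1_rate, 0.5)
  expect_equal(one$label, "SC")
  three <- classify_participant(p, "three_criteria")
  expect_false(three$criterion1_pass)
  # all liked-unhealthy items accepted -> rate 0 -> NSC in one-criterion mode
  p2 <- make_profile(health = c(-2, -1, -2, 1, 2, 1),
                     taste = c(2, 1, 1, 2, 1, 2),
                     decision = c(2, 1, 2, 2, 1, 2))
  r2 <- classify_participant(p2, "one_criterion")
  expect_equal(r2$criterion1_rate, 0)
  expect_equal(r2$label, "NSC")
  # zero self-control-required trials -> unclassified with diagnostic
  p3 <- make_profile(health = c(1, 2, 1, 2), taste = c(1, 2, 2, 1),
                     decision = c(1, 1, -1, 2))
  r3 <- classify_participant(p3, "three_criteria")
  expect_equal(r3$label, "unclassified")
  expect_match(r3$diagnostic, "no usable")
})

test_that("classification is invariant to stimulus order", {
  set.seed(3)
  cfg <- sim_config()
  st <- simulate_stimuli(cfg)
  p <- simulate_subject(cfg, st, "SC")
  perm <- sample(nrow(p))
  for (mode in c("three_criteria", "one_criterion")) {
    a <- classify_participant(p, mode)
    b <- classify_participant(p[perm, ], mode)
    expect_identical(a$label, b$label)
    expect_equal(a$criterion1_rate, b$criterion1_rate)
  }
})

test_that("group choice table handles identical groups and perfect agreement", {
  set.seed(4)
  cfg <- quiet_config()
  st <- simulate_stimuli(cfg)
  base <- lapply(1:6, function(i) simulate_subject(cfg, st, "SC"))
  # identical groups: every t statistic 0, p 1, correlations 1
  g <- group_choice_table(c(base, base), rep(c("SC", "NSC"), each = 6))
  ok <- !is.na(g$proportions$t)   # categories with scorable stimuli
  expect_gte(sum(ok), 3)
  expect_true(all(abs(g$proportions$t[ok]) < 1e-12))
  expect_true(all(g$proportions$p[ok] > 1 - 1e-12))
  expect_true(all(g$rating_correlations$r > 1 - 1e-12))
  expect_error(group_choice_table(base, rep("SC", 6)), "non-empty")
})

test_that("group choice test keeps its nominal level under label permutation", {
  set.seed(5)
  cfg <- sim_config()
  st <- simulate_stimuli(cfg)
  profiles <- lapply(1:30, function(i) simulate_subject(cfg, st, "NSC"))
  n_perm <- 500
  rej <- logical(n_perm)
  for (i in seq_len(n_perm)) {
    lab <- sample(rep(c("SC", "NSC"), each = 15))
    g <- group_choice_table(profiles, lab)
    rej[i] <- g$proportions$p[g$proportions$category == "liked_unhealthy"] < 0.05
  }
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)
})
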