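test_that("keypresses are binned into half-open 2-s intervals", {
  d <- code_intervals(c(1.0, 7.5), NULL, duration = 10)
  expect_equal(d$response, c(1L, 0L, 0L, 1L, 0L))
  # two presses in one interval stay a single binary response
  d2 <- code_intervals(c(0.2, 1.9), NULL, duration = 10)
  expect_equal(d2$response, c(1L, 0L, 0L, 0L, 0L))
  # a press exactly on a boundary belongs to the later interval
  d3 <- code_intervals(2.0, NULL, duration = 10)
  expect_equal(d3$response, c(0L, 1L, 0L, 0L, 0L))
  # the full movie duration yields the published interval count
  d4 <- code_intervals(numeric(0), NULL, duration = 1964)
  expect_equal(nrow(d4), 982L)
  expect_true(all(d4$response == 0L))
  expect_error(code_intervals(-1, NULL, 10), "negative")
  expect_error(code_intervals(1, NULL, 0), "duration")
})

test_that("change annotations produce counts and type indicators per interval", {
  ann <- data.frame(time = c(0.5, 1.2, 3.0, 3.5), type = c(1, 4, 4, 9))
  d <- code_intervals(numeric(0), ann, duration = 8)
  expect_equal(d$count_changes, c(2L, 2L, 0L, 0L))
  expect_equal(d$change_type_1, c(1L, 0L, 0L, 0L))
  expect_equal(d$change_type_4, c(1L, 1L, 0L, 0L))
  expect_equal(d$change_type_9, c(0L, 1L, 0L, 0L))
})

test_that("boundary-interval rows equal intervals containing a press (random sets)", {
  set.seed(31)
  for (rep in 1:20) {
    dur <- sample(20:60, 1)
    presses <- runif(sample(0:15, 1), 0, dur)
    d <- code_intervals(presses, NULL, duration = dur)
    brute <- vapply(seq_len(nrow(d)), function(i)
      any(presses >= (i - 1) * 2 & presses < i * 2), logical(1))
    expect_equal(d$response == 1L, brute)
  }
})

test_that("odds ratios reproduce published coefficient-OR pairs", {
  expect_lt(abs(odds_ratio(0.438, 0.1)$or - 1.550), 0.001)
  expect_lt(abs(odds_ratio(-0.954, 0.1)$or - 0.385), 0.001)
  expect_lt(abs(odds_ratio(-0.132, 0.1)$or - 0.876), 0.001)
})

test_that("odds-ratio CIs are symmetric about the OR on the log scale", {
  o <- odds_ratio(0.7, 0.21)
  expect_equal(o$or, exp(0.7))
  expect_equal(sqrt(o$ci_low * o$ci_high), o$or, tolerance = 1e-12)
  o0 <- odds_ratio(0, 0.3)
  expect_equal(o0$or, 1)
  expect_equal(o0$ci_low * o0$ci_high, 1, tolerance = 1e-12)
  expect_error(odds_ratio(1, 0), "se")
})

test_that("slope z-test matches the normal CDF and is antisymmetric", {
  eq <- compare_slopes_z(0.4, 0.1, 0.4, 0.2)
  expect_equal(eq$z, 0)
  expect_equal(eq$p, 1)
  zz <- compare_slopes_z(1, sqrt(0.5), 0, sqrt(0.5))
  expect_equal(zz$z, 1)
  expect_equal(zz$p, 2 * pnorm(-1), tolerance = 1e-12)
  a <- compare_slopes_z(0.438, 0.012, 0.306, 0.018)
  b <- compare_slopes_z(0.306, 0.018, 0.438, 0.012)
  expect_equal(a$z, -b$z)
  expect_error(compare_slopes_z(1, 0, 1, 1), "positive")
})

test_that("VIF matches the precision-matrix oracle and flags exact collinearity", {
  set.seed(8)
  X <- matrix(rnorm(600), 200, 3)
  X[, 2] <- 0.8 * X[, 1] + sqrt(1 - 0.64) * X[, 2]
  v <- compute_vif(X)
  oracle <- diag(solve(cor(X)))   # VIF identity for standardized predictors
  expect_equal(unname(v), unname(oracle), tolerance = 1e-8)
  # exactly orthogonal, centered pair
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100), 50, 2))))[, 2:3]
  expect_equal(unname(compute_vif(Q)), c(1, 1), tolerance = 1e-10)
  Xd <- cbind(X, X[, 1])
  expect_true(any(is.infinite(compute_vif(Xd))))
  expect_error(compute_vif(cbind(1, X[, 1])), "constant")
})

test_that("segment lengths and the pooled t-test reproduce the published df", {
  set.seed(12)
  presses <- lapply(1:79, function(i) cumsum(runif(20, 1, 5)))
  lens <- segment_length_stats(presses)
  a <- lens[1:40]; b <- lens[41:79]
  ht <- group_ttest(a, b)
  expect_equal(ht$df, 77)
  expect_equal(group_ttest(a, a)$t, 0, tolerance = 1e-12)
  expect_warning(segment_length_stats(list(c(1, 2, 3), 5)), "excluded")
})

test_that("the t-test attains nominal power for a unit shift at the study size", {
  set.seed(77)
  hits <- 0
  for (r in 1:200) {
    a <- rnorm(40, 1); b <- rnorm(39, 0)
    if (group_ttest(a, b)$p < 0.05) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.95)
})

test_that("rank-sum statistic equals the pooled rank sum of the first sample", {
  rs <- rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$statistic, 6)  # minimal possible rank sum for n1 = 3
  same <- rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_gt(same$p, 0.99)
  set.seed(5)
  a <- runif(12); b <- runif(15)
  raw <- rank_sum(a, b)
  tr <- rank_sum(exp(a), exp(b))   # monotone transform leaves ranks alone
  expect_equal(raw$statistic, tr$statistic)
  expect_equal(raw$p, tr$p)
  expect_error(rank_sum(numeric(0), 1), "non-empty")
})

test_that("count-model fit recovers generating effects on reduced synthetic data", {
  p <- behavior_sim_params(n_subjects_per_group = c(15, 15), n_intervals = 300)
  d <- simulate_segmentation_behavior(p, seed = 21)
  fit <- fit_count_model(d)
  expect_s3_class(fit, "glmm_fit")
  expect_true(fit$converged)
  est <- fit$fixed_effects
  sl <- est[est$term == "count_changes", ]
  expect_lt(abs(sl$estimate - 0.306), 3 * sl$se)
  expect_equal(fit$n_obs, nrow(d))
  pg <- fit_count_model(d, by_group = TRUE)
  expect_named(pg, c("adolescent", "adult"))
  expect_gt(pg$adult$fixed_effects$estimate[2], 0)
})

test_that("count-model estimates with zero random-intercept SD match plain glm", {
  p <- behavior_sim_params(n_subjects_per_group = c(10, 10), n_intervals = 300,
                           random_intercept_sd = 0)
  d <- simulate_segmentation_behavior(p, seed = 22)
  fit <- fit_count_model(d)
  ref <- glm(response ~ count_changes * group, binomial(), data = d)
  expect_equal(unname(fit$fixed_effects$estimate),
               unname(coef(ref)), tolerance = 1e-3)
})

test_that("type model flags rank deficiency naming the offending column", {
  p <- behavior_sim_params(n_subjects_per_group = c(8, 8), n_intervals = 200,
                           type_effects = rep(0, 9), type_rates = rep(0.2, 9))
  d <- simulate_segmentation_behavior(p, seed = 23)
  d$change_type_9 <- d$change_type_1
  expect_error(fit_type_model(d), "change_type_9")
  d2 <- simulate_segmentation_behavior(p, seed = 24)
  d2$change_type_5 <- 0L
  expect_error(fit_type_model(d2), "change_type_5")
})

test_that("type model estimates per-type odds ratios on synthetic data", {
  p <- behavior_sim_params(n_subjects_per_group = c(12, 12), n_intervals = 400,
                           type_effects = c(1.2, rep(0, 8)),
                           type_rates = rep(0.25, 9))
  d <- simulate_segmentation_behavior(p, seed = 25)
  fit <- fit_type_model(d)
  ors <- fit$odds_ratios
  t1 <- ors[ors$term == "change_type_1", ]
  expect_gt(t1$ci_low, 1)          # the injected effect is detected
  expect_equal(nrow(fit$fixed_effects), 20)  # 1 + group + 9 types + 9 interactions
})
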