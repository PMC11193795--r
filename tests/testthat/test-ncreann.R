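# Quick config for unit tests; the structure-recovery suite exercises the
# full default configuration.
fast_cfg <- function(...) ncreann_config(folds = 3, max_epochs = 60,
                                         patience = 10, ...)

test_that("information criteria recover a linear VAR(3) order", {
  A <- array(0, c(3, 2, 2))
  A[1, 1, 1] <- 0.4; A[1, 2, 1] <- 0.3; A[2, 2, 2] <- 0.25
  A[3, 1, 2] <- -0.35
  sys <- mvar_system(2, 3, A)
  hits_bic <- hits_aic <- 0
  for (sd in 1:10) {
    x <- simulate_nl_mvar(sys, 5000, seed = sd)
    sel <- select_order(x, max_order = 6)
    hits_bic <- hits_bic + (sel$bic_order == 3)
    hits_aic <- hits_aic + (sel$aic_order >= 3)
  }
  expect_gte(hits_bic, 8)
  expect_gte(hits_aic, 8)
})

test_that("white noise prefers order 0 or 1 and boundary orders warn", {
  x <- simulate_nl_mvar(mvar_system(2, 1), 3000, seed = 5)
  sel <- select_order(x, max_order = 5)
  expect_lte(sel$bic_order, 1)
  A <- array(0, c(3, 2, 2))
  A[1, 1, 1] <- 0.4; A[1, 2, 1] <- 0.3; A[2, 2, 2] <- 0.25
  A[3, 1, 2] <- -0.35
  deep <- simulate_nl_mvar(mvar_system(2, 3, A), 4000, seed = 6)
  expect_warning(sel2 <- select_order(deep, max_order = 2), "max_order")
  expect_equal(sel2$aic_order, 2)
})

test_that("training is deterministic given the seed", {
  x <- simulate_nl_mvar(make_benchmark_system("mixed3"), 1200, seed = 1)
  m1 <- ncreann_train(x, 2, fast_cfg(), seed = 42)
  m2 <- ncreann_train(x, 2, fast_cfg(), seed = 42)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$metrics, m2$metrics)
  m3 <- ncreann_train(x, 2, fast_cfg(), seed = 43)
  expect_false(identical(m1$W1, m3$W1))
})

test_that("test R-squared approaches the predictable fraction of a linear VAR(1)", {
  # x2(n) = 0.7 x1(n-1) + e: predictable variance fraction of channel 2 is
  # 0.49/1.49; channel 1 is pure noise, so the two-channel R2 is half that.
  A <- array(0, c(1, 2, 2)); A[1, 2, 1] <- 0.7
  x <- simulate_nl_mvar(mvar_system(2, 1, A), 6000, seed = 9)
  m <- ncreann_train(x, 1, fast_cfg(), seed = 2)
  want <- (0.49 / 1.49) / 2
  expect_lt(abs(mean(m$metrics$test_r2) - want), 0.05)
})

test_that("white-noise training yields near-zero test R-squared", {
  x <- simulate_nl_mvar(mvar_system(2, 1), 4000, seed = 10)
  m <- ncreann_train(x, 2, fast_cfg(), seed = 3)
  expect_lt(abs(mean(m$metrics$test_r2)), 0.05)
})

test_that("the Taylor split is an exact decomposition of the network", {
  x <- simulate_nl_mvar(make_benchmark_system("mixed3"), 1500, seed = 2)
  m <- ncreann_train(x, 2, fast_cfg(), seed = 7)
  split <- taylor_split(m)
  set.seed(1)
  X <- matrix(rnorm(200 * 6), 200, 6)
  f <- segconn:::nn_forward(m[c("W1", "b1", "W2", "b2")], X)
  expect_equal(split$f_lin(X) + split$f_nonlin(X), f, tolerance = 1e-12)
})

test_that("the nonlinear remainder vanishes as hidden weights shrink", {
  m <- list(W1 = matrix(1e-4, 4, 2), b1 = rep(0.1, 4),
            W2 = matrix(1, 1, 4), b2 = 0)
  split <- taylor_split(m)
  X <- matrix(seq(-2, 2, length.out = 40), ncol = 2)
  expect_lt(max(abs(split$f_nonlin(X))), 1e-6)
})

test_that("a purely linear fit has a small nonlinear share on held-out inputs", {
  A <- array(0, c(1, 2, 2)); A[1, 2, 1] <- 0.7; A[1, 1, 1] <- 0.5
  x <- simulate_nl_mvar(mvar_system(2, 1, A), 6000, seed = 3)
  m <- ncreann_train(x, 1, fast_cfg(), seed = 4)
  split <- taylor_split(m)
  datz <- (x$data - m$center) / m$scale
  ld <- segconn:::lag_design(datz, 1)
  hold <- ld$X[5001:5999, ]
  ratio <- sqrt(sum(split$f_nonlin(hold)^2) / sum(split$f_lin(hold)^2))
  expect_lt(ratio, 0.1)
})

test_that("linear connectivity is invariant under hidden-unit relabeling", {
  x <- simulate_nl_mvar(make_benchmark_system("mixed3"), 1500, seed = 4)
  m <- ncreann_train(x, 2, fast_cfg(), seed = 8)
  lc <- linear_connectivity(m)
  perm <- sample(ncol(m$W2))
  m$W1 <- m$W1[perm, ]; m$b1 <- m$b1[perm]; m$W2 <- m$W2[, perm]
  expect_equal(linear_connectivity(m), lc, tolerance = 1e-12)
})

test_that("linear connectivity tracks OLS VAR coefficient magnitudes", {
  sys <- make_benchmark_system("linear3")
  x <- simulate_nl_mvar(sys, 4000, seed = 12)
  m <- ncreann_train(x, 1, fast_cfg(), seed = 5)
  lc <- linear_connectivity(m)
  d <- (x$data - m$center) / m$scale
  N <- ncol(d) - 1
  # coefficient rows are predictors (sources), columns targets — the same
  # orientation as the connectivity matrix
  ols <- abs(stats::lm.fit(t(d[, 1:N]), t(d[, 2:(N + 1)]))$coefficients)
  off <- !diag(3)
  expect_gte(cor(lc[off], ols[off], method = "spearman"), 0.8)
})

test_that("NC is exactly zero when the network has no nonlinear part", {
  x <- simulate_nl_mvar(mvar_system(2, 1), 1500, seed = 6)
  m <- ncreann_train(x, 1, fast_cfg(), seed = 9)
  # zero hidden input weights make f purely affine: restricted == full
  m$W1[] <- 0
  for (f in seq_along(m$fold_models)) m$fold_models[[f]]$weights$W1[] <- 0
  nc <- nonlinear_connectivity(m, x)
  expect_identical(nc[1, 2], 0)
  expect_identical(nc[2, 1], 0)
})

test_that("time-shifted surrogates preserve marginals and circular autocovariance", {
  x <- simulate_nl_mvar(make_benchmark_system("mixed3"), 1000, seed = 7)
  surr <- time_shift_surrogates(x, n = 5, seed = 3)
  circ_acov1 <- function(v) mean((v - mean(v)) *
                                   ((c(v[-1], v[1])) - mean(v)))
  for (s in surr) {
    for (ch in 1:3) {
      expect_equal(sort(s$data[ch, ]), sort(x$data[ch, ]))
      expect_equal(circ_acov1(s$data[ch, ]), circ_acov1(x$data[ch, ]),
                   tolerance = 1e-12)
    }
  }
  expect_identical(time_shift_surrogates(x, 5, seed = 3)[[1]]$data,
                   surr[[1]]$data)
})

test_that("time shifting destroys the cross-correlation of a coupled pair", {
  x <- simulate_nl_mvar(make_benchmark_system("mixed3"), 2000, seed = 8)
  peak <- function(d) max(abs(ccf(d[1, ], d[2, ], lag.max = 5,
                                  plot = FALSE)$acf))
  surr <- time_shift_surrogates(x, n = 21, seed = 4)
  drops <- vapply(surr, function(s) peak(s$data) / peak(x$data), numeric(1))
  expect_lt(median(drops), 0.5)
})

test_that("group averaging keeps only surrogate-significant connections", {
  mk <- function(lc, lc_surr_max) {
    M <- nrow(lc)
    lc_surr <- array(rep(seq(0, 1, length.out = 100), each = M * M) *
                       rep(lc_surr_max, 100), c(M, M, 100))
    lc_surr <- aperm(lc_surr, c(3, 1, 2))
    thr <- apply(lc_surr, c(2, 3), quantile, 0.9, names = FALSE)
    structure(list(lc = lc, nc = lc, lc_surr = lc_surr, nc_surr = lc_surr,
                   lc_sig = lc > thr, nc_sig = lc > thr,
                   percentile = 90), class = "connectivity_result")
  }
  M <- 2
  base_max <- matrix(1, M, M)
  r_lo <- mk(matrix(0.1, M, M), base_max)    # below all surrogates
  expect_true(all(!r_lo$lc_sig))
  g <- significance_and_average(list(r_lo, r_lo))
  expect_true(all(g$lc[!diag(M)] == 0))
  r_hi <- mk(matrix(2, M, M), base_max)      # above all surrogates
  g2 <- significance_and_average(list(r_hi, r_lo), scale = 100)
  expect_equal(g2$lc[1, 2], 200)             # mean over contributing subjects
  expect_equal(g2$lc_n[1, 2], 1L)
})

test_that("a value beating exactly 90 of 100 surrogates is retained", {
  surr <- seq_len(100)                      # order stats 1..100
  thr <- quantile(surr, 0.9, names = FALSE) # 90.1 under type-7 interpolation
  v <- 91                                   # exceeds exactly 90 surrogates
  expect_true(v > thr)
  expect_false(90.05 > thr)                 # inside the interpolation gap
})
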