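#' Training configuration for the nonlinear MVAR network
#'
#' Hyperparameters of the incremental gradient-descent trainer with
#' momentum. The default schedule is a small constant learning rate with
#' tail averaging: the returned weights are the mean of the last
#' `avg_tail` epoch-end snapshots, which bracket the early-stopping
#' optimum and average out the per-sample gradient noise. Because the
#' schedule does not react to how learnable the data are, real fits and
#' time-shifted surrogate fits share the same weight-noise floor, which
#' keeps the surrogate significance threshold calibrated (see the
#' package vignette).
#'
#' Two classic alternatives are available through the configuration: a
#' geometric rate decay (`lr_decay` per epoch, floored at `eta_min`) and
#' a performance-reactive adaptive rule — with non-neutral `lr_up`,
#' `lr_down`, `err_ratio`, an epoch that lowers the training MSE
#' multiplies the rate by `lr_up`, and an epoch that raises it by more
#' than `err_ratio - 1` is discarded and the rate multiplied by
#' `lr_down`. The reactive rule is off by default: its realized rate
#' depends on the data, which biases the surrogate comparison.
#'
#' Training stops when the validation MSE has not improved for
#' `patience` epochs, or at `max_epochs`. Each of `folds` folds draws a
#' fresh random permutation of the samples and splits it `split`
#' (train/validation/test); the best-validation fold supplies the
#' returned weights.
#'
#' @param hidden hidden-layer size (default 10).
#' @param eta initial learning rate (default 0.002).
#' @param momentum momentum coefficient (default 0.5).
#' @param lr_up,lr_down,err_ratio performance-reactive rate rule;
#'   neutral (`1`, `1`, `Inf`) by default.
#' @param lr_decay per-epoch geometric rate decay (default 1, none).
#' @param eta_min learning-rate floor (default 1e-5).
#' @param max_epochs,patience stopping controls (defaults 150 and 15).
#' @param folds number of permuted cross-validation folds (default 10).
#' @param split train/validation/test fractions, must sum to 1.
#' @param init_range weights initialized uniformly in
#'   `[-init_range, init_range]` (default 0.5).
#' @param avg_tail epochs entering the tail average of the returned
#'   weights (default 15; 0 returns the best-validation snapshot).
#' @return object of class `ncreann_config`.
#' @export
ncreann_config <- function(hidden = 10, eta = 0.002, momentum = 0.5,
                           lr_up = 1, lr_down = 1, err_ratio = Inf,
                           lr_decay = 1, eta_min = 1e-5,
                           max_epochs = 150, patience = 15, folds = 10,
                           split = c(0.8, 0.1, 0.1), init_range = 0.5,
                           avg_tail = 15) {
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  if (folds < 2) stop("folds must be >= 2")
  structure(as.list(environment()), class = "ncreann_config")
}

# Lagged design: row n is [x1(n-1), ..., xM(n-1), x1(n-2), ..., xM(n-p)],
# target row n is x(n). Data matrix is M x T.
lag_design <- function(dat, order) {
  M <- nrow(dat); T_ <- ncol(dat)
  N <- T_ - order
  X <- matrix(0, N, M * order)
  for (k in seq_len(order))
    X[, (k - 1) * M + seq_len(M)] <- t(dat[, (order - k) + seq_len(N),
                                           drop = FALSE])
  list(X = X, Y = t(dat[, order + seq_len(N), drop = FALSE]))
}

#' Select the MVAR model order by information criteria
#'
#' Fits ordinary least-squares linear VAR models of order 0..`max_order`
#' on a common sample window and returns the Akaike- and
#' Schwarz/Bayesian-criterion minimizers. The full pipeline defaults to
#' order 10; for orders above the true one the network's linear
#' coefficients at the surplus lags shrink toward zero, so over-ordering
#' is benign.
#'
#' @param data a [ts_set()].
#' @param max_order largest candidate order.
#' @return list `aic_order`, `bic_order`, `table` (order, aic, bic).
#' @export
select_order <- function(data, max_order) {
  stopifnot(inherits(data, "ts_set"))
  dat <- data$data
  M <- nrow(dat); T_ <- ncol(dat)
  if (T_ <= 10 * max_order * M)
    stop("too few samples for the requested max_order")
  N <- T_ - max_order
  Yfull <- t(dat[, max_order + seq_len(N), drop = FALSE])
  tab <- data.frame(order = 0:max_order, aic = NA_real_, bic = NA_real_)
  for (p in 0:max_order) {
    if (p == 0) {
      E <- sweep(Yfull, 2, colMeans(Yfull))
    } else {
      X <- matrix(0, N, M * p)
      for (k in seq_len(p))
        X[, (k - 1) * M + seq_len(M)] <-
          t(dat[, (max_order - k) + seq_len(N), drop = FALSE])
      fit <- stats::lm.fit(cbind(1, X), Yfull)
      E <- as.matrix(fit$residuals)
    }
    Sig <- crossprod(E) / N
    k_par <- p * M * M
    ld <- determinant(Sig, logarithm = TRUE)$modulus
    tab$aic[p + 1] <- ld + 2 * k_par / N
    tab$bic[p + 1] <- ld + log(N) * k_par / N
  }
  aic_order <- tab$order[which.min(tab$aic)]
  bic_order <- tab$order[which.min(tab$bic)]
  if (aic_order == max_order || bic_order == max_order)
    warning("selected order hit max_order; the true order may be larger")
  list(aic_order = aic_order, bic_order = bic_order, table = tab)
}

nn_forward <- function(w, X) {
  H <- tanh(X %*% t(w$W1) + rep(w$b1, each = nrow(X)))
  H %*% t(w$W2) + rep(w$b2, each = nrow(X))
}

# First-order expansion of the network about x_p = 0:
# f_lin(x) = [b2 + W2 tanh(b1)] + [W2 diag(1 - tanh(b1)^2) W1] x
nn_linear_part <- function(w) {
  th <- tanh(w$b1)
  list(A = w$W2 %*% (w$W1 * (1 - th^2)),
       c = drop(w$b2 + w$W2 %*% th))
}

#' Fit the nonlinear MVAR network
#'
#' Standardizes each channel to zero mean and unit variance, builds the
#' lag design of the requested order, and trains the one-hidden-layer
#' network (tanh hidden units, linear outputs) by incremental
#' backpropagation with momentum, adaptive learning rate, early stopping
#' and permuted cross-validation (see [ncreann_config()]). The
#' best-validation fold's weights become the model; every fold's weights
#' and test indices are retained for residual-based statistics.
#'
#' @param data a [ts_set()].
#' @param order model order p (lags).
#' @param config an [ncreann_config()].
#' @param seed integer seed controlling initialization, sample order and
#'   fold permutations; identical seeds give identical weights.
#' @return object of class `ncreann_model`: weights `W1`, `b1`, `W2`,
#'   `b2`, standardization `center`/`scale`, `order`, `n_signals`,
#'   `metrics` (per-fold train/val/test MSE and R-squared),
#'   `fold_models`, `best_fold`, `config`.
#' @export
ncreann_train <- function(data, order, config = ncreann_config(), seed = 1) {
  stopifnot(inherits(data, "ts_set"), inherits(config, "ncreann_config"))
  dat <- data$data
  M <- nrow(dat); T_ <- ncol(dat)
  if (!all(is.finite(dat))) stop("non-finite values in the input series")
  if (T_ <= 20 * M * order)
    stop("series too short: need more than 20 * M * order samples")
  ctr <- rowMeans(dat); scl <- apply(dat, 1, stats::sd)
  if (any(scl == 0)) stop("constant channel cannot be standardized")
  datz <- (dat - ctr) / scl
  ld <- lag_design(datz, order)
  N <- nrow(ld$X)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_tr <- floor(config$split[1] * N)
  n_val <- floor(config$split[2] * N)
  folds <- vector("list", config$folds)
  metrics <- data.frame(fold = seq_len(config$folds), train_mse = NA_real_,
                        val_mse = NA_real_, test_mse = NA_real_,
                        train_r2 = NA_real_, test_r2 = NA_real_,
                        epochs = NA_integer_)
  r2_of <- function(w, idx) {
    Yh <- nn_forward(w, ld$X[idx, , drop = FALSE])
    Yt <- ld$Y[idx, , drop = FALSE]
    1 - sum((Yt - Yh)^2) / sum(sweep(Yt, 2, colMeans(Yt))^2)
  }
  for (f in seq_len(config$folds)) {
    perm <- sample.int(N)
    i_tr <- perm[seq_len(n_tr)]
    i_val <- perm[n_tr + seq_len(n_val)]
    i_te <- perm[(n_tr + n_val + 1):N]
    fit <- .train_mlp_cpp(ld$X, ld$Y, config$hidden, i_tr, i_val,
                          config$eta, config$momentum, config$lr_up,
                          config$lr_down, config$err_ratio,
                          config$lr_decay, config$eta_min,
                          config$max_epochs, config$patience,
                          config$init_range, config$avg_tail)
    w <- list(W1 = fit$W1, b1 = drop(fit$b1), W2 = fit$W2,
              b2 = drop(fit$b2))
    metrics$train_mse[f] <- fit$train_mse
    metrics$val_mse[f] <- fit$val_mse
    metrics$test_mse[f] <- mean((nn_forward(w, ld$X[i_te, , drop = FALSE]) -
                                   ld$Y[i_te, , drop = FALSE])^2)
    metrics$train_r2[f] <- r2_of(w, i_tr)
    metrics$test_r2[f] <- r2_of(w, i_te)
    metrics$epochs[f] <- fit$epochs
    folds[[f]] <- list(weights = w, test_idx = i_te)
  }
  best <- which.min(metrics$val_mse)
  wbest <- folds[[best]]$weights
  structure(
    list(W1 = wbest$W1, b1 = wbest$b1, W2 = wbest$W2, b2 = wbest$b2,
         center = ctr, scale = scl, order = order, n_signals = M,
         metrics = metrics, fold_models = folds, best_fold = best,
         config = config),
    class = "ncreann_model")
}

#' @export
print.ncreann_model <- function(x, ...) {
  cat(sprintf("<ncreann_model> M=%d, order=%d, hidden=%d; best fold %d (val MSE %.4f, test R2 %.3f)\n",
              x$n_signals, x$order, x$config$hidden, x$best_fold,
              min(x$metrics$val_mse), x$metrics$test_r2[x$best_fold]))
  invisible(x)
}

#' Split the fitted mapping into linear and nonlinear parts
#'
#' First-order Taylor expansion of each hidden unit about its bias point
#' yields an affine `f_lin`; the remainder `f_nonlin = f - f_lin` holds
#' all higher-order terms, so `f_lin(x) + f_nonlin(x)` reproduces the
#' network output exactly for every input.
#'
#' @param model an [ncreann_train()] model (or a bare weight list).
#' @return list of two functions, `f_lin(X)` and `f_nonlin(X)`, both
#'   taking an `n x (M * order)` matrix of standardized lag vectors and
#'   returning `n x M` predictions.
#' @export
taylor_split <- function(model) {
  w <- model[c("W1", "b1", "W2", "b2")]
  lin <- nn_linear_part(w)
  f_lin <- function(X)
    sweep(X %*% t(lin$A), 2, lin$c, "+")
  f_nonlin <- function(X) nn_forward(w, X) - f_lin(X)
  list(f_lin = f_lin, f_nonlin = f_nonlin)
}

#' Linear directed connectivity from the fitted network
#'
#' The linear gain from signal i at lag k to output j is the
#' weight-path product through the hidden layer,
#' `g[j,i,k] = sum_h W2[j,h] tanh'(b1[h]) W1[h,(i,k)]`. The linear
#' connectivity from i to j averages `|g|` over all lags. Values are in
#' standardized-signal units; the diagonal is `NA`.
#'
#' @param model an `ncreann_model`.
#' @return M x M matrix `lc` with `lc[i, j]` the linear influence of
#'   signal i on signal j.
#' @export
linear_connectivity <- function(model) {
  stopifnot(inherits(model, "ncreann_model"))
  M <- model$n_signals; p <- model$order
  A <- nn_linear_part(model)$A      # M x (M p), rows = targets
  lc <- matrix(0, M, M)
  for (i in seq_len(M)) {
    cols <- (seq_len(p) - 1) * M + i
    lc[i, ] <- rowMeans(abs(A[, cols, drop = FALSE]))
  }
  diag(lc) <- NA_real_
  dimnames(lc) <- list(names(model$center), names(model$center))
  lc
}

#' Nonlinear directed connectivity from estimation-error ratios
#'
#' For each ordered pair i -> j, the full model's residual on held-out
#' samples is compared with the residual of a restricted prediction in
#' which signal i reaches target j only linearly: the nonlinear pathway
#' sees i's lags replaced by their (zero) standardized mean, while the
#' linear part is untouched. The connectivity is
#' `NC[i,j] = ln(<e_restricted^2> / <e_full^2>)`, computed on each fold's
#' test samples and averaged over folds. A system with no nonlinear
#' i -> j influence gives NC near 0.
#'
#' @param model an `ncreann_model`.
#' @param data the [ts_set()] the model was trained on.
#' @return M x M matrix `nc` with the diagonal `NA`.
#' @export
nonlinear_connectivity <- function(model, data) {
  stopifnot(inherits(model, "ncreann_model"), inherits(data, "ts_set"))
  M <- model$n_signals; p <- model$order
  datz <- (data$data - model$center) / model$scale
  ld <- lag_design(datz, p)
  acc <- matrix(0, M, M)
  for (fm in model$fold_models) {
    w <- fm$weights
    split <- taylor_split(w)
    X <- ld$X[fm$test_idx, , drop = FALSE]
    Y <- ld$Y[fm$test_idx, , drop = FALSE]
    flin <- split$f_lin(X)
    efull2 <- colMeans((Y - nn_forward(w, X))^2)
    if (any(efull2 == 0)) stop("zero full-model residual variance")
    for (i in seq_len(M)) {
      Xz <- X
      Xz[, (seq_len(p) - 1) * M + i] <- 0
      yr <- flin + (nn_forward(w, Xz) - split$f_lin(Xz))
      er2 <- colMeans((Y - yr)^2)
      acc[i, ] <- acc[i, ] + log(er2 / efull2)
    }
  }
  nc <- acc / length(model$fold_models)
  diag(nc) <- NA_real_
  nc
}

#' Time-shifted surrogate series
#'
#' Each surrogate circularly shifts every channel independently by a
#' uniform random offset in `[0.1 T, 0.9 T]` samples. Per channel, the
#' marginal distribution and circular autocovariance are preserved
#' exactly, while cross-channel (causal) alignment is destroyed.
#'
#' @param data a [ts_set()].
#' @param n number of surrogates (default 100).
#' @param seed integer seed.
#' @return list of `n` [ts_set()] objects.
#' @export
time_shift_surrogates <- function(data, n = 100, seed = 1) {
  stopifnot(inherits(data, "ts_set"))
  T_ <- n_samples(data); M <- n_channels(data)
  lo <- ceiling(0.1 * T_); hi <- floor(0.9 * T_)
  if (lo >= hi) stop("series too short for time-shifted surrogates")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(n), function(s) {
    shifted <- data$data
    for (ch in seq_len(M)) {
      off <- sample(lo:hi, 1)
      shifted[ch, ] <- data$data[ch, c((off + 1):T_, 1:off)]
    }
    ts_set(shifted, sampling_rate = data$sampling_rate,
           channels = data$channels)
  })
}

#' Single-subject connectivity with surrogate significance
#'
#' Trains the network on the data, extracts linear (lC) and nonlinear
#' (NC) connectivity, then repeats the identical procedure (same
#' hyperparameters, fresh random initializations) on `n_surrogates`
#' time-shifted surrogates. A connection is significant when its real
#' value strictly exceeds the stated percentile (linear-interpolation
#' definition) of its own surrogate distribution.
#'
#' @param data a [ts_set()].
#' @param order model order.
#' @param config an [ncreann_config()].
#' @param n_surrogates surrogate count (default 100).
#' @param percentile significance percentile (default 90).
#' @param seed integer seed; surrogate fits use seeds derived from it.
#' @return object of class `connectivity_result`: `lc`, `nc`,
#'   `lc_surr`/`nc_surr` (n_surrogates x M x M), `lc_sig`/`nc_sig`
#'   logical masks, `model`, `percentile`.
#' @export
ncreann_connectivity <- function(data, order, config = ncreann_config(),
                                 n_surrogates = 100, percentile = 90,
                                 seed = 1) {
  model <- ncreann_train(data, order, config, seed = seed)
  lc <- linear_connectivity(model)
  nc <- nonlinear_connectivity(model, data)
  M <- model$n_signals
  lc_surr <- nc_surr <- array(NA_real_, c(n_surrogates, M, M))
  surr <- time_shift_surrogates(data, n_surrogates, seed = seed + 1L)
  for (s in seq_len(n_surrogates)) {
    ms <- ncreann_train(surr[[s]], order, config, seed = seed + 1L + s)
    lc_surr[s, , ] <- linear_connectivity(ms)
    nc_surr[s, , ] <- nonlinear_connectivity(ms, surr[[s]])
  }
  thr <- function(a) apply(a, c(2, 3), function(v)
    if (all(is.na(v))) NA_real_
    else stats::quantile(v, probs = percentile / 100, names = FALSE))
  lc_sig <- lc > thr(lc_surr)
  nc_sig <- nc > thr(nc_surr)
  structure(
    list(lc = lc, nc = nc, lc_surr = lc_surr, nc_surr = nc_surr,
         lc_sig = lc_sig, nc_sig = nc_sig, model = model,
         percentile = percentile),
    class = "connectivity_result")
}

#' @export
print.connectivity_result <- function(x, ...) {
  cat(sprintf("<connectivity_result> M=%d, %d surrogates, %d significant lC / %d significant NC edge(s)\n",
              nrow(x$lc), dim(x$lc_surr)[1],
              sum(x$lc_sig, na.rm = TRUE), sum(x$nc_sig, na.rm = TRUE)))
  invisible(x)
}

#' Group-average significant connectivity
#'
#' Per subject and connection, significance is the strict exceedance of
#' that connection's surrogate percentile (already stored in each
#' subject's result). The group matrix averages the significant subjects'
#' values (non-significant subjects contribute nothing; a connection
#' significant in no subject is 0) and applies the presentation scale
#' factor.
#'
#' @param results list of per-subject `connectivity_result`s sharing one
#'   region set.
#' @param scale presentation scale factor (default 100).
#' @return list with scaled group matrices `lc`/`nc`, subject counts
#'   `lc_n`/`nc_n` per connection, and `n_subjects`.
#' @export
significance_and_average <- function(results, scale = 100) {
  stopifnot(length(results) >= 1)
  M <- nrow(results[[1]]$lc)
  if (!all(vapply(results, function(r) nrow(r$lc) == M, TRUE)))
    stop("subjects have mismatched region sets")
  lc_sum <- nc_sum <- matrix(0, M, M)
  lc_n <- nc_n <- matrix(0L, M, M)
  for (r in results) {
    ls <- r$lc_sig & !is.na(r$lc); ns <- r$nc_sig & !is.na(r$nc)
    ls[is.na(ls)] <- FALSE; ns[is.na(ns)] <- FALSE
    lc_sum[ls] <- lc_sum[ls] + r$lc[ls]
    nc_sum[ns] <- nc_sum[ns] + r$nc[ns]
    lc_n <- lc_n + ls; nc_n <- nc_n + ns
  }
  lc <- ifelse(lc_n > 0, lc_sum / lc_n, 0) * scale
  nc <- ifelse(nc_n > 0, nc_sum / nc_n, 0) * scale
  diag(lc) <- diag(nc) <- NA_real_
  list(lc = lc, nc = nc, lc_n = lc_n, nc_n = nc_n,
       n_subjects = length(results), scale = scale)
}

#' Write a connectivity result to JSON
#' @param x a `connectivity_result`.
#' @param path JSON path.
#' @param scale presentation scale applied to the matrices (default 100).
#' @return `path`, invisibly.
#' @export
write_connectivity_result <- function(x, path, scale = 100) {
  obj <- list(
    regions = rownames(x$lc) %||% paste0("R", seq_len(nrow(x$lc))),
    lc = x$lc * scale, nc = x$nc * scale,
    lc_significant = x$lc_sig, nc_significant = x$nc_sig,
    percentile = x$percentile, scale = scale,
    n_surrogates = dim(x$lc_surr)[1],
    surrogate_lc_p90 = apply(x$lc_surr, c(2, 3), function(v)
      if (all(is.na(v))) NA_real_
      else stats::quantile(v, x$percentile / 100, names = FALSE)) * scale,
    surrogate_nc_p90 = apply(x$nc_surr, c(2, 3), function(v)
      if (all(is.na(v))) NA_real_
      else stats::quantile(v, x$percentile / 100, names = FALSE)) * scale,
    metrics = x$model$metrics,
    config = unclass(x$model$config))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
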