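#' Specify a nonlinear multivariate autoregressive (MVAR) system
#'
#' Defines the ground-truth generative model
#' \deqn{x(n) = f(x_p) + \sigma(n)}
#' where \eqn{x_p} stacks the previous `order` samples of all `n_signals`
#' series. `f` is the sum of a linear VAR part and an explicit list of
#' nonlinear terms (squares or pairwise products of lagged samples), and
#' \eqn{\sigma(n)} is white Gaussian innovation noise.
#'
#' @param n_signals number of signals M.
#' @param order number of lags p.
#' @param linear_coefs numeric array `order x n_signals x n_signals`;
#'   entry `[k, j, i]` is the weight of signal i at lag k on signal j.
#' @param nonlinear_terms list of terms; each a list with fields
#'   `target` (j), `source` (i), `lag` (k), `kind` (`"square"` or
#'   `"product"`), `weight`, and for products `source2`/`lag2`.
#' @param noise_sd innovation standard deviation, scalar or length M.
#' @return An object of class `mvar_system`.
#' @details The linear part must be stationary: the spectral radius of its
#'   companion matrix must be below 1. Nonlinear terms may still cause
#'   divergence for large weights; [simulate_nl_mvar()] guards against that
#'   at run time.
#' @export
mvar_system <- function(n_signals, order, linear_coefs = NULL,
                        nonlinear_terms = list(), noise_sd = 1) {
  if (is.null(linear_coefs))
    linear_coefs <- array(0, dim = c(order, n_signals, n_signals))
  linear_coefs <- as.array(linear_coefs)
  if (!identical(dim(linear_coefs), as.integer(c(order, n_signals, n_signals))))
    stop("linear_coefs must be an order x M x M array")
  noise_sd <- rep_len(noise_sd, n_signals)
  if (any(noise_sd < 0)) stop("noise_sd must be non-negative")
  for (tm in nonlinear_terms) {
    stopifnot(tm$kind %in% c("square", "product"))
    if (tm$lag > order || tm$lag < 1) stop("nonlinear term lag exceeds order")
    if (identical(tm$kind, "product") &&
        (is.null(tm$source2) || is.null(tm$lag2)))
      stop("product terms need source2 and lag2")
    if (identical(tm$kind, "product") && tm$lag2 > order)
      stop("nonlinear term lag exceeds order")
    if (tm$target > n_signals || tm$source > n_signals)
      stop("nonlinear term indexes a signal beyond M")
  }
  structure(
    list(n_signals = n_signals, order = order, linear_coefs = linear_coefs,
         nonlinear_terms = nonlinear_terms, noise_sd = noise_sd),
    class = "mvar_system"
  )
}

#' @export
print.mvar_system <- function(x, ...) {
  cat(sprintf("<mvar_system> M=%d, order=%d, %d nonlinear term(s), rho=%.3f\n",
              x$n_signals, x$order, length(x$nonlinear_terms),
              companion_spectral_radius(x)))
  invisible(x)
}

#' Spectral radius of the companion form of the linear part
#'
#' @param system an `mvar_system`.
#' @return largest eigenvalue modulus of the `(M*p) x (M*p)` companion
#'   matrix; values below 1 mean the linear VAR part is stationary.
#' @export
companion_spectral_radius <- function(system) {
  M <- system$n_signals; p <- system$order
  comp <- matrix(0, M * p, M * p)
  for (k in seq_len(p))
    comp[seq_len(M), (k - 1) * M + seq_len(M)] <- system$linear_coefs[k, , ]
  if (p > 1)
    comp[M + seq_len(M * (p - 1)), seq_len(M * (p - 1))] <-
      diag(M * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a nonlinear MVAR system
#'
#' Iterates the system from a zero state, discards a burn-in of
#' `10 * order` samples to remove the initialization transient, and
#' returns the requested number of samples.
#'
#' @param system an [mvar_system()].
#' @param n_samples samples to return (after burn-in); must exceed
#'   `10 * order`.
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @param sampling_rate stored in the result, defaults to 1 Hz.
#' @return a [ts_set()] of `n_signals x n_samples`.
#' @export
simulate_nl_mvar <- function(system, n_samples, seed, sampling_rate = 1) {
  stopifnot(inherits(system, "mvar_system"))
  M <- system$n_signals; p <- system$order
  if (n_samples <= 10 * p) stop("n_samples must exceed 10 * order")
  rho <- companion_spectral_radius(system)
  if (rho >= 1)
    stop(sprintf("non-stationary linear part: companion spectral radius %.3f >= 1",
                 rho))
  burn <- 10 * p
  total <- n_samples + burn
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  eps <- matrix(stats::rnorm(M * total), M, total) * system$noise_sd
  x <- matrix(0, M, total)
  A <- system$linear_coefs
  for (n in seq_len(total)) {
    xn <- eps[, n]
    kmax <- min(p, n - 1)
    for (k in seq_len(kmax))
      xn <- xn + A[k, , ] %*% x[, n - k]
    if (n > p) {
      for (tm in system$nonlinear_terms) {
        v <- x[tm$source, n - tm$lag]
        contrib <- if (identical(tm$kind, "square")) tm$weight * v^2
                   else tm$weight * v * x[tm$source2, n - tm$lag2]
        xn[tm$target] <- xn[tm$target] + contrib
      }
    }
    if (any(abs(xn) > 1e6))
      stop(sprintf("simulation diverged at sample %d (|x| > 1e6); check nonlinear term weights", n))
    x[, n] <- xn
  }
  ts_set(x[, burn + seq_len(n_samples), drop = FALSE],
         sampling_rate = sampling_rate)
}

# Save/restore the global RNG state so seeded generators leave no footprint.
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Benchmark MVAR systems with known directed structure
#'
#' Fixtures for validating connectivity estimators against ground truth.
#' \describe{
#'   \item{linear3}{3 signals, purely linear chain:
#'     x2 <- 0.5 x1(n-1), x3 <- 0.4 x2(n-1).}
#'   \item{mixed3}{3 signals: x1 driven by noise only;
#'     x2 <- 0.5 x1(n-1) (linear edge 1->2);
#'     x3 <- 0.4 x2(n-1)^2 (nonlinear edge 2->3).}
#'   \item{mixed4}{4 signals adding a product interaction
#'     x4 <- 0.3 x1(n-1) x2(n-2) + 0.35 x3(n-1) on top of mixed3's edges.}
#' }
#' All innovations are unit-variance Gaussian.
#'
#' @param name one of `"linear3"`, `"mixed3"`, `"mixed4"`.
#' @return an [mvar_system()].
#' @export
make_benchmark_system <- function(name = c("linear3", "mixed3", "mixed4")) {
  name <- match.arg(name)
  if (name == "linear3") {
    A <- array(0, c(1, 3, 3))
    A[1, 2, 1] <- 0.5
    A[1, 3, 2] <- 0.4
    return(mvar_system(3, 1, A))
  }
  if (name == "mixed3") {
    A <- array(0, c(1, 3, 3))
    A[1, 2, 1] <- 0.5
    nl <- list(list(target = 3, source = 2, lag = 1, kind = "square",
                    weight = 0.4))
    return(mvar_system(3, 1, A, nl))
  }
  A <- array(0, c(2, 4, 4))
  A[1, 2, 1] <- 0.5
  A[1, 4, 3] <- 0.35
  nl <- list(
    list(target = 3, source = 2, lag = 1, kind = "square", weight = 0.4),
    list(target = 4, source = 1, lag = 1, kind = "product",
         source2 = 2, lag2 = 2, weight = 0.3))
  mvar_system(4, 2, A, nl)
}

#' True directed edge sets of a benchmark system
#'
#' @param system an `mvar_system`.
#' @return list with logical M x M matrices `linear` and `nonlinear`
#'   marking the ground-truth directed edges (row = source, col = target).
#' @export
true_edges <- function(system) {
  M <- system$n_signals
  lin <- matrix(FALSE, M, M)
  for (k in seq_len(system$order))
    lin <- lin | (t(system$linear_coefs[k, , ]) != 0)
  diag(lin) <- FALSE
  nl <- matrix(FALSE, M, M)
  for (tm in system$nonlinear_terms) {
    nl[tm$source, tm$target] <- TRUE
    if (identical(tm$kind, "product")) nl[tm$source2, tm$target] <- TRUE
  }
  diag(nl) <- FALSE
  list(linear = lin, nonlinear = nl)
}

#' Serialize / deserialize an MVAR system as JSON
#' @param system an `mvar_system`.
#' @param path JSON file path.
#' @return `write_mvar_system` returns `path` invisibly;
#'   `read_mvar_system` an `mvar_system`.
#' @export
write_mvar_system <- function(system, path) {
  obj <- list(
    n_signals = system$n_signals, order = system$order,
    linear_coefs = system$linear_coefs,
    nonlinear_terms = system$nonlinear_terms,
    noise_sd = system$noise_sd)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mvar_system
#' @export
read_mvar_system <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nl <- obj$nonlinear_terms
  if (is.data.frame(nl)) nl <- lapply(seq_len(nrow(nl)), function(i)
    as.list(nl[i, !vapply(nl[i, ], function(v) is.null(v) || all(is.na(v)), TRUE)]))
  if (is.null(nl)) nl <- list()
  A <- array(unlist(obj$linear_coefs),
             dim = c(obj$order, obj$n_signals, obj$n_signals))
  mvar_system(obj$n_signals, obj$order, A, nl, obj$noise_sd)
}
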