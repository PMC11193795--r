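#' Partial correlation with a t-based p-value
#'
#' Correlates the residuals of `x` and `y` after ordinary least-squares
#' regression on the control variables. With no controls this is the
#' plain Pearson correlation. The p-value uses the t transform
#' `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - k` for `k` controls.
#'
#' @param x,y numeric vectors of equal length.
#' @param controls numeric matrix (columns = control variables) or `NULL`.
#' @return list `r`, `p`, `df`.
#' @export
partial_corr <- function(x, y, controls = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  k <- if (is.null(controls)) 0L else ncol(as.matrix(controls))
  if (n <= k + 2) stop("need more observations than controls + 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (constant) input")
  if (k > 0) {
    Z <- as.matrix(controls)
    if (nrow(Z) != n) stop("controls must have the same number of rows")
    x <- stats::lm.fit(cbind(1, Z), x)$residuals
    y <- stats::lm.fit(cbind(1, Z), y)$residuals
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("inputs are fully explained by the controls")
  }
  r <- stats::cor(x, y)
  df <- n - 2 - k
  tval <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  list(r = r, p = 2 * stats::pt(-abs(tval), df), df = df)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (q-values); monotone over the sorted input
#' and order-equivariant.
#'
#' @param p_values numeric vector in `[0, 1]`.
#' @return numeric vector of q-values, same order as the input.
#' @export
fdr_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Link connectivity strengths to behavioral slopes
#'
#' Computes, per connection, the partial correlation between a vector of
#' per-subject connectivity strengths and per-subject behavioral
#' sensitivity (e.g., count-model slopes), with FDR correction over all
#' connections tested. Controls default to none; pass confounds
#' explicitly when they are known.
#'
#' @param connectivity numeric matrix, subjects x connections (named
#'   columns recommended).
#' @param behavior numeric vector of per-subject behavioral measures.
#' @param controls optional subjects x k matrix of covariates.
#' @return data.frame with `connection`, `r`, `p`, `q`.
#' @export
link_connectivity_behavior <- function(connectivity, behavior,
                                       controls = NULL) {
  connectivity <- as.matrix(connectivity)
  if (nrow(connectivity) != length(behavior))
    stop("connectivity rows must match behavior length")
  if (is.null(colnames(connectivity)))
    colnames(connectivity) <- paste0("conn_", seq_len(ncol(connectivity)))
  if (is.null(controls))
    warning("no control variables supplied; computing plain correlations")
  res <- lapply(seq_len(ncol(connectivity)), function(j)
    partial_corr(connectivity[, j], behavior, controls))
  out <- data.frame(connection = colnames(connectivity),
                    r = vapply(res, `[[`, numeric(1), "r"),
                    p = vapply(res, `[[`, numeric(1), "p"))
  out$q <- fdr_adjust(out$p)
  out
}
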