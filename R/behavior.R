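#' Code keypresses and situational changes into 2-s intervals
#'
#' Splits a recording of `duration` seconds into consecutive intervals of
#' `interval_length` seconds (half-open, `[start, start + len)`; a press
#' exactly on a boundary belongs to the later interval). An interval is a
#' boundary interval (response = 1) iff it contains at least one keypress.
#' Situational-change annotations are counted per interval regardless of
#' type, and each of the nine types gets a presence indicator.
#'
#' @param keypress_times numeric vector of press times in seconds.
#' @param change_annotations data.frame with columns `time` (seconds) and
#'   `type` (integer 1..9); may have zero rows.
#' @param duration recording duration in seconds (> 0).
#' @param interval_length interval duration in seconds, default 2.
#' @return data.frame with columns `interval_index`, `count_changes`,
#'   `change_type_1` .. `change_type_9`, `response`;
#'   `floor(duration / interval_length)` rows.
#' @export
code_intervals <- function(keypress_times, change_annotations = NULL,
                           duration, interval_length = 2) {
  if (duration <= 0) stop("duration must be positive")
  if (length(keypress_times) && any(keypress_times < 0))
    stop("negative keypress times")
  if (length(keypress_times) && any(keypress_times > duration))
    stop("keypress times beyond the recording duration")
  n_int <- floor(duration / interval_length)
  resp <- integer(n_int)
  if (length(keypress_times)) {
    idx <- floor(keypress_times / interval_length) + 1
    idx <- idx[idx <= n_int]            # presses after the last full interval
    resp[unique(idx)] <- 1L
  }
  count <- integer(n_int)
  types <- matrix(0L, n_int, 9,
                  dimnames = list(NULL, paste0("change_type_", 1:9)))
  if (!is.null(change_annotations) && nrow(change_annotations)) {
    stopifnot(all(c("time", "type") %in% names(change_annotations)))
    if (any(change_annotations$type < 1 | change_annotations$type > 9))
      stop("change type must be in 1..9")
    ci <- floor(change_annotations$time / interval_length) + 1
    keep <- ci <= n_int & change_annotations$time >= 0
    ci <- ci[keep]; ty <- change_annotations$type[keep]
    tab <- table(factor(ci, levels = seq_len(n_int)))
    count <- as.integer(tab)
    for (r in seq_along(ci)) types[ci[r], ty[r]] <- 1L
  }
  data.frame(interval_index = seq_len(n_int), count_changes = count,
             types, response = resp)
}

glmm_fit_result <- function(fit, terms = NULL) {
  co <- summary(fit)$coefficients
  if (!is.null(terms)) co <- co[terms, , drop = FALSE]
  fe <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                   z = co[, 3], p = co[, 4], row.names = NULL)
  ors <- do.call(rbind, lapply(seq_len(nrow(fe)), function(i) {
    o <- odds_ratio(fe$estimate[i], fe$se[i])
    data.frame(term = fe$term[i], or = o$or, ci_low = o$ci_low,
               ci_high = o$ci_high)
  }))
  msgs <- fit@optinfo$conv$lme4$messages
  structure(
    list(fixed_effects = fe, odds_ratios = ors,
         random_intercept_sd = sqrt(unname(lme4::VarCorr(fit)[[1]][1, 1])),
         n_obs = stats::nobs(fit),
         converged = fit@optinfo$conv$opt == 0 && is.null(msgs),
         messages = if (is.null(msgs)) character() else msgs),
    class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf("<glmm_fit> n = %d, random-intercept SD = %.3f%s\n",
              x$n_obs, x$random_intercept_sd,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  df <- merge(x$fixed_effects, x$odds_ratios, by = "term", sort = FALSE)
  print(df, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Mixed-effects logistic regression of responses on change counts
#'
#' Fits `response ~ count_changes * group + (1 | subject_id)` by maximum
#' likelihood (Laplace approximation, [lme4::glmer()]), or with
#' `by_group = TRUE` one model `response ~ count_changes + (1 | subject_id)`
#' per group — the per-group parameterization whose intercept and slope
#' are directly comparable across groups.
#'
#' Non-convergence is reported through the `converged` flag (and
#' `messages`), never by raising, so simulation batches keep running.
#'
#' @param data a behavioral dataset (see [simulate_segmentation_behavior()]
#'   or [read_behavioral_dataset()]).
#' @param by_group fit separate per-group models instead of the
#'   interaction model.
#' @return a `glmm_fit` (or with `by_group = TRUE` a list with elements
#'   `adolescent` and `adult`): fixed effects with Wald SEs and p-values,
#'   odds ratios with 95% CIs, random-intercept SD, `n_obs`, `converged`.
#' @export
fit_count_model <- function(data, by_group = FALSE) {
  need <- c("subject_id", "group", "count_changes", "response")
  stopifnot(all(need %in% names(data)))
  # The count model's likelihood depends on the data only through the
  # per-(subject, count) response totals, so Bernoulli rows are collapsed
  # to binomial counts before fitting; the MLE and Wald SEs are identical.
  agg <- stats::aggregate(response ~ subject_id + group + count_changes,
                          data = data,
                          FUN = function(v) c(succ = sum(v), n = length(v)))
  agg <- cbind(agg[, 1:3], as.data.frame(agg$response))
  n_obs <- nrow(data)
  if (by_group) {
    fit1 <- function(d) {
      if (length(unique(d$subject_id)) < 2)
        stop("need at least 2 subjects per group")
      out <- glmm_fit_result(suppressMessages(lme4::glmer(
        cbind(succ, n - succ) ~ count_changes + (1 | subject_id),
        data = d, family = stats::binomial())))
      out$n_obs <- sum(d$n)
      out
    }
    return(list(adolescent = fit1(agg[agg$group == 0, ]),
                adult = fit1(agg[agg$group == 1, ])))
  }
  if (any(tapply(data$subject_id, data$group,
                 function(s) length(unique(s))) < 2))
    stop("need at least 2 subjects per group")
  fit <- suppressMessages(lme4::glmer(
    cbind(succ, n - succ) ~ count_changes * group + (1 | subject_id),
    data = agg, family = stats::binomial()))
  out <- glmm_fit_result(fit)
  out$n_obs <- n_obs
  out
}

#' Mixed-effects logistic regression on the nine change types
#'
#' Fits `response ~ group * (type_1 + ... + type_9) + (1 | subject_id)`:
#' nine type main effects, group, and nine type-by-group interactions,
#' with a subject random intercept. Odds ratios with 95% CIs are returned
#' per predictor.
#'
#' @param data behavioral dataset containing `change_type_1` ..
#'   `change_type_9`.
#' @return a `glmm_fit`.
#' @export
fit_type_model <- function(data) {
  tcols <- paste0("change_type_", 1:9)
  stopifnot(all(c("subject_id", "group", "response", tcols) %in% names(data)))
  rhs <- paste0("group * (", paste(tcols, collapse = " + "), ")")
  form <- stats::as.formula(paste("response ~", rhs, "+ (1 | subject_id)"))
  mm <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data)
  const <- apply(mm[, -1, drop = FALSE], 2, function(v) stats::var(v) == 0)
  if (any(const))
    stop("rank-deficient design: constant predictor column(s): ",
         paste(names(const)[const], collapse = ", "))
  qr_ <- qr(mm)
  if (qr_$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_$pivot[(qr_$rank + 1):ncol(mm)]]
    stop("rank-deficient design: collinear predictor column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressMessages(lme4::glmer(
    form, data = data, family = stats::binomial()))
  glmm_fit_result(fit)
}

#' Odds ratio with Wald 95% confidence interval
#'
#' @param estimate fixed-effect estimate on the log-odds scale.
#' @param se its standard error (> 0).
#' @return list `or`, `ci_low`, `ci_high`; `or = exp(estimate)` and the CI
#'   is `exp(estimate +/- 1.96 se)`, so the geometric mean of the bounds
#'   equals the OR exactly.
#' @export
odds_ratio <- function(estimate, se) {
  if (se <= 0) stop("se must be positive")
  list(or = exp(estimate), ci_low = exp(estimate - 1.96 * se),
       ci_high = exp(estimate + 1.96 * se))
}

#' z-test for the difference of two regression coefficients
#'
#' Standard Wald contrast for coefficients estimated in independent
#' groups: `z = (b1 - b2) / sqrt(se1^2 + se2^2)`.
#'
#' @param b1,se1 coefficient and SE of group 1.
#' @param b2,se2 coefficient and SE of group 2.
#' @return list `z`, `p` (two-sided standard normal).
#' @export
compare_slopes_z <- function(b1, se1, b2, se2) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be positive")
  z <- (b1 - b2) / sqrt(se1^2 + se2^2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Variance inflation factors of a design matrix
#'
#' VIF of predictor k is `1 / (1 - R^2_k)` with `R^2_k` from the ordinary
#' regression of column k on all other columns (plus an intercept).
#' Exact collinearity yields `Inf`.
#'
#' @param design_matrix numeric matrix of predictors (no intercept
#'   column).
#' @return named numeric vector of VIFs.
#' @export
compute_vif <- function(design_matrix) {
  X <- as.matrix(design_matrix)
  if (ncol(X) < 2) stop("need at least 2 predictors")
  if (any(apply(X, 2, stats::var) == 0))
    stop("constant column passed; remove intercepts before calling")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  vapply(seq_len(ncol(X)), function(k) {
    # a perfect fit is the documented Inf case, not a warning condition
    r2 <- suppressWarnings(
      summary(stats::lm(X[, k] ~ X[, -k, drop = FALSE]))$r.squared)
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(colnames(X))
}

#' Mean segment length per subject
#'
#' The mean duration of the segments a subject indicated, i.e. the mean of
#' successive inter-press intervals. Subjects with fewer than two presses
#' have no defined segment and are dropped with a warning.
#'
#' @param keypress_times list of numeric vectors, one per subject.
#' @return named numeric vector of per-subject mean lengths (seconds).
#' @export
segment_length_stats <- function(keypress_times) {
  if (is.null(names(keypress_times)))
    names(keypress_times) <- paste0("S", seq_along(keypress_times))
  ok <- vapply(keypress_times, function(v) length(v) >= 2, TRUE)
  if (any(!ok))
    warning(sum(!ok), " subject(s) with < 2 presses excluded")
  vapply(keypress_times[ok], function(v) mean(diff(sort(v))), numeric(1))
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with `df = n1 + n2 - 2` (equal-variance pooling), the form
#' matching a between-groups comparison of per-subject means.
#'
#' @param a,b numeric samples.
#' @return list `t`, `df`, `p` (two-sided).
#' @export
group_ttest <- function(a, b) {
  ht <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Two-sided Wilcoxon rank-sum test (normal approximation)
#'
#' Reports the rank sum of the first sample in the pooled ranking and the
#' two-sided p-value from the normal approximation with tie correction.
#'
#' @param a,b non-empty numeric samples.
#' @return list `statistic` (rank sum of `a`), `p`.
#' @export
rank_sum <- function(a, b) {
  if (!length(a) || !length(b)) stop("samples must be non-empty")
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = FALSE))
  n1 <- length(a)
  list(statistic = unname(ht$statistic) + n1 * (n1 + 1) / 2,
       p = ht$p.value)
}

#' Write a GLMM fit to JSON
#' @param fit a `glmm_fit`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_glmm_fit <- function(fit, path) {
  jsonlite::write_json(unclass(fit), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
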