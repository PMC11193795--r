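#' Parameters for simulating grouped segmentation behavior
#'
#' Defines a two-group (adolescent = 0, adult = 1) mixed-effects logistic
#' generative model for boundary responses in 2-s movie intervals. Per
#' subject and interval, a situational-change count is drawn from
#' `change_count_distribution`, the response log-odds are
#' `intercept + count_slope * count + group_effect * group +
#' interaction * count * group + type effects + subject intercept`,
#' and the boundary response is Bernoulli.
#'
#' Defaults reproduce the published per-group logistic coefficients
#' (adolescents: intercept -3.342, slope 0.306; adults: -2.399, 0.438),
#' expressed with adolescent as reference: `group_effect = 0.943`,
#' `interaction = 0.132`. The count distribution defaults to the observed
#' interval frequencies of 0..5 changes (518/278/106/52/29/4, normalized).
#'
#' @param n_subjects_per_group integer; either one count for both groups
#'   or length 2 `(adolescent, adult)`. Default `c(39, 40)`.
#' @param n_intervals intervals per subject (default 982).
#' @param intercept,count_slope,group_effect,interaction fixed effects on
#'   the logit scale.
#' @param type_effects optional length-9 vector of situational-change-type
#'   log-odds effects; `NULL` disables type simulation.
#' @param type_rates length-9 Bernoulli occurrence rates of the nine change
#'   types per interval (used only when `type_effects` is given); the
#'   indicators are drawn independently.
#' @param random_intercept_sd subject random-intercept SD in logit units.
#' @param change_count_distribution probability vector over counts 0..5.
#' @return object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(
    n_subjects_per_group = c(39, 40),
    n_intervals = 982,
    intercept = -3.342, count_slope = 0.306,
    group_effect = 0.943, interaction = 0.132,
    type_effects = NULL,
    type_rates = rep(0.1, 9),
    random_intercept_sd = 0.5,
    change_count_distribution = c(518, 278, 106, 52, 29, 4) / 987) {
  n_subjects_per_group <- rep_len(as.integer(n_subjects_per_group), 2)
  if (n_intervals <= 0) stop("n_intervals must be positive")
  if (any(change_count_distribution < 0) ||
      abs(sum(change_count_distribution) - 1) > 1e-8)
    stop("change_count_distribution must be a probability vector")
  if (!is.null(type_effects) && length(type_effects) != 9)
    stop("type_effects must have length 9")
  if (length(type_rates) != 9) stop("type_rates must have length 9")
  if (random_intercept_sd < 0) stop("random_intercept_sd must be >= 0")
  structure(
    list(n_subjects_per_group = n_subjects_per_group,
         n_intervals = as.integer(n_intervals),
         intercept = intercept, count_slope = count_slope,
         group_effect = group_effect, interaction = interaction,
         type_effects = type_effects, type_rates = type_rates,
         random_intercept_sd = random_intercept_sd,
         change_count_distribution = change_count_distribution),
    class = "behavior_sim_params")
}

#' Simulate grouped boundary-response data
#'
#' @param params a [behavior_sim_params()].
#' @param seed integer seed.
#' @return data.frame of class `behavioral_dataset` with columns
#'   `subject_id`, `group` (0 adolescent / 1 adult), `interval_index`,
#'   `count_changes`, `change_type_1` .. `change_type_9` (when type
#'   simulation is on), `response` (1 = boundary interval).
#' @export
simulate_segmentation_behavior <- function(params, seed = 1) {
  stopifnot(inherits(params, "behavior_sim_params"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ns <- params$n_subjects_per_group
  n_sub <- sum(ns)
  group <- rep(c(0L, 1L), ns)
  subj_int <- stats::rnorm(n_sub, 0, params$random_intercept_sd)
  ni <- params$n_intervals
  rows <- vector("list", n_sub)
  with_types <- !is.null(params$type_effects)
  for (s in seq_len(n_sub)) {
    count <- sample(0:5, ni, replace = TRUE,
                    prob = params$change_count_distribution)
    logit <- params$intercept + params$count_slope * count +
      params$group_effect * group[s] +
      params$interaction * count * group[s] + subj_int[s]
    df <- data.frame(subject_id = sprintf("S%03d", s), group = group[s],
                     interval_index = seq_len(ni), count_changes = count)
    if (with_types) {
      types <- matrix(stats::rbinom(ni * 9, 1, rep(params$type_rates,
                                                   each = ni)), ni, 9)
      colnames(types) <- paste0("change_type_", 1:9)
      logit <- logit + drop(types %*% params$type_effects)
      df <- cbind(df, types)
    }
    df$response <- stats::rbinom(ni, 1, stats::plogis(logit))
    rows[[s]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("behavioral_dataset", "data.frame")
  out
}

#' Write / read a behavioral dataset as tab-separated text
#' @param data a `behavioral_dataset` data.frame.
#' @param path TSV path.
#' @return `write_behavioral_dataset` returns `path` invisibly;
#'   `read_behavioral_dataset` the data.frame.
#' @export
write_behavioral_dataset <- function(data, path) {
  utils::write.table(data, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavioral_dataset
#' @export
read_behavioral_dataset <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  class(out) <- c("behavioral_dataset", "data.frame")
  out
}

#' Serialize / deserialize behavior simulation parameters as JSON
#' @param params a `behavior_sim_params` object.
#' @param path JSON path.
#' @return `write_behavior_sim_params` returns `path` invisibly;
#'   `read_behavior_sim_params` the parameter object.
#' @export
write_behavior_sim_params <- function(params, path) {
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_behavior_sim_params
#' @export
read_behavior_sim_params <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(behavior_sim_params, obj[!vapply(obj, is.null, TRUE)])
}
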