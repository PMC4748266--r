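# A metric that is undefined for the given data is returned as NA_real_
# carrying a "flag" attribute (and, where informative, the raw numerator).
# Batch evaluation then reports the flag instead of silently propagating NaN.
undefined_metric <- function(flag, numerator = NULL) {
  structure(NA_real_, flag = flag, numerator = numerator)
}

#' Diagnostic flag of a metric value
#'
#' Metrics that are undefined for the given data (e.g. a non-positive signal
#' power estimate, or a constant prediction) return `NA` carrying a flag
#' naming the reason. `metric_flag` retrieves it (`NULL` for a defined
#' value).
#'
#' @param x a value returned by one of the metric functions.
#' @return a character flag such as `"SP_NONPOSITIVE"`, or `NULL`.
#' @export
metric_flag <- function(x) attr(x, "flag")

#' Total response power
#'
#' The average, over trials, of the variance (across time bins) of a single
#' trial's spike counts: `TP = (1/N) * sum_n Var(R_n)`. This is the total
#' power of the recording, which splits into a stimulus-locked signal part
#' and a trial-to-trial noise part (see [signal_power()]).
#'
#' @param trials a [trial_matrix()].
#' @return total power in (counts/bin)^2, using the sample variance
#'   (denominator `T - 1`).
#' @export
total_power <- function(trials) {
  trials <- as_trial_matrix(trials)
  mean(apply(unclass(trials), 1, var))
}

#' Signal/noise power decomposition of a trial matrix
#'
#' Splits the total power `TP` of repeated-trial responses into the signal
#' power `SP` — the part of the PSTH variance that is locked to the stimulus
#' and hence explainable in principle by a model — and the noise power
#' `NP = TP - SP` reflecting trial-to-trial variability. `SP` is estimated
#' from inter-trial agreement as
#' `SP = (Var(sum_n R_n) - sum_n Var(R_n)) / (N (N - 1))`,
#' an unbiased estimator under additive stimulus-independent noise.
#'
#' On noisy data with few trials the estimate can come out zero or negative;
#' such a decomposition is flagged invalid (`sp_is_valid = FALSE`) and every
#' metric that divides by `SP` refuses to produce a number for it.
#'
#' @param trials a [trial_matrix()] with at least 2 trials.
#' @return an object of class `power_decomposition`: list with elements
#'   `tp`, `sp`, `np`, `n_trials`, `sp_is_valid`.
#' @export
signal_power <- function(trials) {
  trials <- as_trial_matrix(trials)
  n <- nrow(trials)
  if (n < 2) stop("signal power needs at least 2 trials", call. = FALSE)
  m <- unclass(trials)
  tp <- mean(apply(m, 1, var))
  sp <- (var(colSums(m)) - sum(apply(m, 1, var))) / (n * (n - 1))
  structure(list(tp = tp, sp = sp, np = tp - sp,
                 n_trials = n, sp_is_valid = sp > 0),
            class = "power_decomposition")
}

#' @export
print.power_decomposition <- function(x, ...) {
  cat(sprintf("Power decomposition over %d trials\n", x$n_trials))
  cat(sprintf("  total power  TP = %.6g\n", x$tp))
  cat(sprintf("  signal power SP = %.6g%s\n", x$sp,
              if (x$sp_is_valid) "" else "  [non-positive: noise-dominated]"))
  cat(sprintf("  noise power  NP = %.6g\n", x$np))
  invisible(x)
}

#' Coefficient of determination
#'
#' `CD = 1 - sum((y - y_hat)^2) / sum(y^2)`: the residual sum of squares
#' relative to the raw sum of squares of the observation. Unlike [cc_abs()]
#' or [variance_explained()], CD penalizes a constant bias in the prediction
#' heavily, since the bias accumulates over every bin.
#'
#' @param y observed rate series (the PSTH).
#' @param yhat predicted rate series of the same length.
#' @return a number `<= 1`; undefined (flag `ZERO_OBSERVATION`) if `y` is
#'   all zeros.
#' @export
coefficient_of_determination <- function(y, yhat) {
  y <- as_numeric_rate(y); yhat <- as_numeric_rate(yhat)
  check_same_length(y, yhat)
  ss <- sum(y^2)
  if (ss == 0) return(undefined_metric("ZERO_OBSERVATION"))
  1 - sum((y - yhat)^2) / ss
}

#' Proportion of variance explained
#'
#' `VE = 1 - Var(y - y_hat) / Var(y)`. Mean-subtracted, so insensitive to a
#' constant bias in the prediction; still confounded by trial-to-trial noise
#' in `y` (see [spe()] for the noise-corrected version).
#'
#' @inheritParams coefficient_of_determination
#' @return a number `<= 1`; undefined (flag `CONSTANT_PSTH`) if `y` is
#'   constant.
#' @export
variance_explained <- function(y, yhat) {
  y <- as_numeric_rate(y); yhat <- as_numeric_rate(yhat)
  check_same_length(y, yhat)
  vy <- var(y)
  if (vy == 0) return(undefined_metric("CONSTANT_PSTH"))
  1 - var(y - yhat) / vy
}

#' Signal power explained (SPE)
#'
#' The explained signal power relative to the explainable signal power:
#' `SPE = (Var(y) - Var(y - y_hat)) / SP`, with `y` the PSTH of the trial
#' matrix and `SP` its signal power. Expanding the variance of the
#' difference gives the equivalent covariance form
#' `SPE = (2 Cov(y, y_hat) - Var(y_hat)) / SP`, which makes the metric's
#' behaviour transparent: a prediction uncorrelated with the data scores
#' `-Var(y_hat)/SP` (negative, unboundedly so as the prediction variance
#' grows), and any constant prediction scores exactly 0. A perfect model
#' scores 1 (100%) in expectation. Negative values are returned as computed
#' and flagged `NEGATIVE_SPE`, never clamped.
#'
#' @param trials a [trial_matrix()] (N >= 2).
#' @param yhat predicted [rate_series()] of length `T`.
#' @param decomposition optionally a precomputed [signal_power()] result.
#' @return SPE as a fraction (1 = all explainable power explained);
#'   undefined with flag `SP_NONPOSITIVE` when the signal-power estimate is
#'   not positive.
#' @export
spe <- function(trials, yhat, decomposition = signal_power(trials)) {
  trials <- as_trial_matrix(trials)
  y <- as_numeric_rate(compute_psth(trials))
  yhat <- as_numeric_rate(yhat)
  check_same_length(y, yhat)
  # constant prediction: Var(yhat) = Cov(y, yhat) = 0 exactly, so SPE = 0
  # exactly (the variance-difference form only reaches 0 up to rounding)
  num <- if (var(yhat) == 0) 0 else var(y) - var(y - yhat)
  if (!decomposition$sp_is_valid) {
    return(undefined_metric("SP_NONPOSITIVE", numerator = num))
  }
  out <- num / decomposition$sp
  if (out < 0) attr(out, "flag") <- "NEGATIVE_SPE"
  out
}

#' SPE in covariance form
#'
#' `(2 Cov(y, y_hat) - Var(y_hat)) / sp` — algebraically identical to
#' [spe()] and exposed separately so the two routes can be cross-checked.
#'
#' @param y observed rate series (PSTH).
#' @param yhat predicted rate series.
#' @param sp signal power (must be positive for a defined result).
#' @return as [spe()].
#' @export
spe_covariance_form <- function(y, yhat, sp) {
  y <- as_numeric_rate(y); yhat <- as_numeric_rate(yhat)
  check_same_length(y, yhat)
  num <- 2 * cov(y, yhat) - var(yhat)
  if (!is.finite(sp) || sp <= 0) {
    return(undefined_metric("SP_NONPOSITIVE", numerator = num))
  }
  out <- num / sp
  if (out < 0) attr(out, "flag") <- "NEGATIVE_SPE"
  out
}

check_same_length <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop(sprintf("length mismatch: observed %d bins, predicted %d bins",
                 length(y), length(yhat)), call. = FALSE)
  }
  invisible(TRUE)
}
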