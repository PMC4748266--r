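#' Evaluate a prediction against repeated-trial responses
#'
#' The main entry point: computes every performance metric in the package
#' for one prediction against one trial matrix — the naive accuracy scores
#' (CD, VE, Pearson's CC_abs), the power decomposition (TP/SP/NP), the
#' noise-ceiling-corrected scores (SPE and CC_norm, the latter by both the
#' closed form and the historical split-half route), and the noise ceiling
#' itself (CC_max by both routes). Degenerate situations (non-positive
#' signal power, constant prediction, non-positive split-half reliability)
#' never abort: the affected scores are reported as undefined with a
#' diagnostic flag.
#'
#' @param trials a [trial_matrix()] (or plain count matrix), `N >= 2`.
#' @param yhat predicted [rate_series()] (or numeric vector) of length `T`.
#' @param n_splits,seed split-half resampling controls, see
#'   [split_half_cc()].
#' @return object of class `metric_report`: list with elements `power`
#'   (the [signal_power()] decomposition), `metrics` (named list of scores,
#'   `NA` where undefined), `flags` (named character vector of diagnostic
#'   flags), `split` (the [split_half_cc()] result) and `provenance`
#'   (parameters used).
#' @examples
#' sim <- simulate_trials(simulation_spec(rate_sinusoid(30, 20, 2),
#'                                        n_trials = 10, duration = 1, seed = 1))
#' rep <- evaluate_prediction(sim$trials, sim$true_rate)
#' rep
#' @export
evaluate_prediction <- function(trials, yhat, n_splits = 126, seed = 0) {
  trials <- as_trial_matrix(trials)
  y <- compute_psth(trials)
  check_same_length(as_numeric_rate(y), as_numeric_rate(yhat))
  dec <- signal_power(trials)
  split <- split_half_cc(trials, n_splits = n_splits, seed = seed)
  cm_split <- cc_max_from_split(split)
  cm_direct <- cc_max_direct(trials, dec)

  vals <- list(
    cd            = coefficient_of_determination(y, yhat),
    ve            = variance_explained(y, yhat),
    spe           = spe(trials, yhat, dec),
    cc_abs        = cc_abs(y, yhat),
    cc_half       = split$cc_half,
    cc_max_split  = cm_split$value,
    cc_max_direct = cm_direct$value,
    cc_norm       = cc_norm(trials, yhat, dec),
    cc_norm_split = cc_norm_via_split(trials, yhat, n_splits = n_splits,
                                      seed = seed)
  )
  flags <- character(0)
  for (nm in names(vals)) {
    f <- metric_flag(vals[[nm]])
    if (!is.null(f)) flags[nm] <- f
  }
  if (!is.null(cm_split$flag)) flags["cc_max_split"] <- cm_split$flag
  if (!is.null(cm_direct$flag)) flags["cc_max_direct"] <- cm_direct$flag
  if (!dec$sp_is_valid) flags["sp"] <- "SP_NONPOSITIVE"

  structure(list(
    power = dec,
    metrics = lapply(vals, function(v) as.numeric(v)[1]),
    flags = flags,
    split = split,
    provenance = list(bin_width = attr(trials, "bin_width"),
                      n_trials = nrow(trials), n_bins = ncol(trials),
                      n_splits = n_splits, seed = seed,
                      exhaustive_splits = split$exhaustive)
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  p <- x$provenance
  cat(sprintf("Model evaluation: %d trials x %d bins (bin width %g s)\n",
              p$n_trials, p$n_bins, p$bin_width))
  cat(sprintf("  TP = %.4g, SP = %.4g, NP = %.4g%s\n",
              x$power$tp, x$power$sp, x$power$np,
              if (x$power$sp_is_valid) "" else " [SP non-positive]"))
  fmt <- function(nm, label) {
    v <- x$metrics[[nm]]
    if (is.na(v)) {
      cat(sprintf("  %-14s undefined [%s]\n", label, x$flags[[nm]]))
    } else {
      cat(sprintf("  %-14s % .*f\n", label, digits, v))
    }
  }
  fmt("cd", "CD"); fmt("ve", "VE"); fmt("spe", "SPE")
  fmt("cc_abs", "CC_abs"); fmt("cc_half", "CC_half")
  fmt("cc_max_split", "CC_max(split)"); fmt("cc_max_direct", "CC_max(direct)")
  fmt("cc_norm", "CC_norm"); fmt("cc_norm_split", "CC_norm(split)")
  invisible(x)
}

#' @export
summary.metric_report <- function(object, ...) {
  print(object, ...)
  if (length(object$flags)) {
    cat("Flags:", paste(sprintf("%s=%s", names(object$flags), object$flags),
                        collapse = ", "), "\n")
  }
  invisible(object)
}

#' Serialize a metric report as JSON
#'
#' Undefined scores are written as explicit JSON `null`s, with the flag
#' strings alongside, so downstream tooling never has to guess at silent
#' `NaN`s.
#'
#' @param report a [evaluate_prediction()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path) {
  stopifnot(inherits(report, "metric_report"))
  out <- list(
    power = list(tp = report$power$tp, sp = report$power$sp,
                 np = report$power$np, n_trials = report$power$n_trials,
                 sp_is_valid = report$power$sp_is_valid),
    metrics = lapply(report$metrics, function(v) if (is.na(v)) NULL else v),
    flags = as.list(report$flags),
    provenance = report$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' Summarize metric reports across a population of units
#'
#' Aggregates reports from many neurons. Undefined scores are excluded from
#' the means but counted; for SPE, both the raw mean and the mean of
#' `max(SPE, 0)` are reported side by side, because a few very negative SPE
#' values can drag the raw population mean down in a way that reflects
#' prediction variance rather than prediction quality. Neither summary is
#' substituted for the other.
#'
#' @param reports list of [evaluate_prediction()] results.
#' @return list of class `population_summary` with per-metric means,
#'   undefined counts, and the two SPE summaries.
#' @export
summarize_population <- function(reports) {
  stopifnot(length(reports) > 0,
            all(vapply(reports, inherits, TRUE, "metric_report")))
  get <- function(nm) vapply(reports, function(r) r$metrics[[nm]], numeric(1))
  spe_v <- get("spe"); ccn <- get("cc_norm")
  structure(list(
    n_units = length(reports),
    mean_spe_raw = mean(spe_v, na.rm = TRUE),
    mean_spe_clamped = mean(pmax(spe_v, 0), na.rm = TRUE),
    n_spe_undefined = sum(is.na(spe_v)),
    mean_cc_norm = mean(ccn, na.rm = TRUE),
    n_cc_norm_undefined = sum(is.na(ccn))
  ), class = "population_summary")
}

#' @export
print.population_summary <- function(x, ...) {
  cat(sprintf("Population summary over %d units\n", x$n_units))
  cat(sprintf("  mean SPE (raw)          %.4f  (%d undefined)\n",
              x$mean_spe_raw, x$n_spe_undefined))
  cat(sprintf("  mean SPE (clamped >= 0) %.4f\n", x$mean_spe_clamped))
  cat(sprintf("  mean CC_norm            %.4f  (%d undefined)\n",
              x$mean_cc_norm, x$n_cc_norm_undefined))
  invisible(x)
}
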