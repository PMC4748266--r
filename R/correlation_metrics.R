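#' Pearson correlation between observed and predicted rate
#'
#' Plain product-moment correlation `Cov(y, y_hat) / sqrt(Var(y) Var(y_hat))`
#' between the PSTH and a prediction. Insensitive to bias and scaling of the
#' prediction, but still bounded above by the noise ceiling set by
#' trial-to-trial variability — see [cc_max_direct()] and [cc_norm()].
#'
#' @param y observed rate series (PSTH).
#' @param yhat predicted rate series of the same length.
#' @return correlation in `[-1, 1]`; undefined with flag
#'   `CONSTANT_PREDICTION` / `CONSTANT_PSTH` when a series has no variance.
#' @export
cc_abs <- function(y, yhat) {
  y <- as_numeric_rate(y); yhat <- as_numeric_rate(yhat)
  check_same_length(y, yhat)
  if (var(y) == 0) return(undefined_metric("CONSTANT_PSTH"))
  if (var(yhat) == 0) return(undefined_metric("CONSTANT_PREDICTION"))
  cor(y, yhat)
}

#' Number of distinct half-splits of N trials
#'
#' For even `N`, the number of unordered partitions into two halves of size
#' `N/2` is `choose(N, N/2) / 2`; for odd `N`, halves have sizes
#' `floor(N/2)` and `ceiling(N/2)` and the count is `choose(N, floor(N/2))`.
#' For `N = 20` this is already 92378, which is why the split-half route to
#' the noise ceiling is laborious compared to the direct one.
#'
#' @param n number of trials (>= 2).
#' @return the number of distinct splits.
#' @export
n_half_splits <- function(n) {
  stopifnot(n >= 2)
  if (n %% 2 == 0) choose(n, n / 2) / 2 else choose(n, floor(n / 2))
}

#' Split-half reliability of a trial matrix
#'
#' Repeatedly partitions the `N` trials into two disjoint halves, builds a
#' PSTH from each half, and correlates the two. The average over splits,
#' `CC_half`, measures how reproducible the recorded response is, and feeds
#' the classical resampling estimate of the noise ceiling
#' ([cc_max_from_split()]).
#'
#' All distinct unordered partitions are enumerated exhaustively when their
#' number is at most `max(n_splits, 1000)`; otherwise `n_splits` distinct
#' random partitions are drawn (seeded, without duplicates). For odd `N` the
#' halves have sizes `floor(N/2)` and `ceiling(N/2)`. Splits in which either
#' half-PSTH is constant carry no correlation and are dropped, counted in
#' `n_dropped`.
#'
#' @param trials a [trial_matrix()] with `N >= 2`.
#' @param n_splits number of random splits when exhaustive enumeration is
#'   too expensive (default 126).
#' @param seed integer seed for the random splits (default 0).
#' @param fisher_z if `TRUE`, aggregate per-split correlations via the
#'   Fisher z-transform instead of the arithmetic mean (default `FALSE`,
#'   matching common practice).
#' @return object of class `split_half`: list with `cc_half`, `per_split`,
#'   `n_splits_used`, `n_dropped`, `exhaustive`, `seed`.
#' @export
split_half_cc <- function(trials, n_splits = 126, seed = 0, fisher_z = FALSE) {
  trials <- as_trial_matrix(trials)
  m <- unclass(trials)
  n <- nrow(m)
  if (n < 2) stop("split-half reliability needs at least 2 trials", call. = FALSE)
  k <- floor(n / 2)
  total <- n_half_splits(n)
  exhaustive <- total <= max(n_splits, 1000)
  if (exhaustive) {
    halves <- enumerate_half_splits(n)
  } else {
    halves <- sample_half_splits(n, n_splits, seed)
  }
  cc <- vapply(halves, function(g) {
    p1 <- colMeans(m[g, , drop = FALSE])
    p2 <- colMeans(m[-g, , drop = FALSE])
    if (var(p1) == 0 || var(p2) == 0) return(NA_real_)
    cor(p1, p2)
  }, numeric(1))
  dropped <- sum(is.na(cc))
  cc <- cc[!is.na(cc)]
  agg <- if (length(cc) == 0) {
    NA_real_
  } else if (fisher_z) {
    tanh(mean(atanh(pmin(pmax(cc, -1 + 1e-15), 1 - 1e-15))))
  } else {
    mean(cc)
  }
  structure(list(cc_half = agg, per_split = cc,
                 n_splits_used = length(cc), n_dropped = dropped,
                 exhaustive = exhaustive, seed = seed),
            class = "split_half")
}

#' @export
print.split_half <- function(x, ...) {
  cat(sprintf("Split-half reliability: CC_half = %.4f over %d splits%s\n",
              x$cc_half, x$n_splits_used,
              if (x$exhaustive) " (exhaustive)" else ""))
  if (x$n_dropped > 0) {
    cat(sprintf("  %d splits dropped (constant half-PSTH)\n", x$n_dropped))
  }
  invisible(x)
}

# All unordered half-partitions, as index vectors of the first group.
# Even n: fix trial 1 in the first group so each partition appears once.
enumerate_half_splits <- function(n) {
  k <- floor(n / 2)
  if (n %% 2 == 0) {
    combos <- utils::combn(seq(2, n), k - 1, simplify = FALSE)
    lapply(combos, function(g) c(1L, g))
  } else {
    utils::combn(seq_len(n), k, simplify = FALSE)
  }
}

sample_half_splits <- function(n, n_splits, seed) {
  k <- floor(n / 2)
  with_local_seed(seed, {
    seen <- new.env(hash = TRUE)
    out <- vector("list", n_splits)
    got <- 0
    attempts <- 0
    while (got < n_splits && attempts < 100 * n_splits) {
      attempts <- attempts + 1
      g <- sort(sample.int(n, k))
      if (n %% 2 == 0 && !(1 %in% g)) g <- sort(setdiff(seq_len(n), g))
      key <- paste(g, collapse = ",")
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      got <- got + 1
      out[[got]] <- g
    }
    out[seq_len(got)]
  })
}

# Run code with a deterministic seed, leaving the caller's RNG untouched.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Noise ceiling from split-half reliability
#'
#' The classical resampling estimate of the maximum correlation any model
#' could achieve against an `N`-trial PSTH:
#' `CC_max = sqrt(2 / (1 + 1/CC_half))`. Monotone increasing in `CC_half`,
#' equal to 1 for perfectly reproducible responses, and tending to 0 as the
#' reliability vanishes. Only defined for `CC_half > 0`.
#'
#' @param cc_half split-half reliability, from [split_half_cc()] (either the
#'   object or the bare number).
#' @return object of class `cc_max`: list with `value`, `route`
#'   (`"split_half"`), `flag` (`NULL` or `"CCHALF_NONPOSITIVE"`).
#' @export
cc_max_from_split <- function(cc_half) {
  if (inherits(cc_half, "split_half")) cc_half <- cc_half$cc_half
  if (!is.finite(cc_half) || cc_half <= 0) {
    return(new_cc_max(NA_real_, "split_half", "CCHALF_NONPOSITIVE"))
  }
  new_cc_max(sqrt(2 / (1 + 1 / cc_half)), "split_half", NULL)
}

#' Noise ceiling computed directly from the power decomposition
#'
#' The closed-form noise ceiling: `CC_max = sqrt(SP / (SP + NP/N))`. This is
#' the correlation between the `N`-trial PSTH and the true underlying firing
#' rate implied by the signal-to-noise ratio of the recording, and replaces
#' the laborious split-half resampling route exactly. Equivalently,
#' `1/CC_max^2 = 1 + (NP/SP)/N`, or in raw sums
#' `CC_max^2 = (V - S) / (V - S + (N-1) S)` with `V = Var(sum_n R_n)` and
#' `S = sum_n Var(R_n)` — all algebraic routes agree to machine precision.
#'
#' @param trials a [trial_matrix()] (N >= 2).
#' @param decomposition optionally a precomputed [signal_power()].
#' @return object of class `cc_max` with `route = "direct"`; undefined with
#'   flag `SP_NONPOSITIVE` when the signal power estimate is not positive.
#' @export
cc_max_direct <- function(trials, decomposition = signal_power(trials)) {
  if (!decomposition$sp_is_valid) {
    return(new_cc_max(NA_real_, "direct", "SP_NONPOSITIVE"))
  }
  g2 <- expected_coherence(decomposition$sp, decomposition$np,
                           decomposition$n_trials)
  new_cc_max(sqrt(g2), "direct", NULL)
}

new_cc_max <- function(value, route, flag) {
  structure(list(value = value, route = route, flag = flag), class = "cc_max")
}

#' @export
print.cc_max <- function(x, ...) {
  if (is.na(x$value)) {
    cat(sprintf("CC_max (%s route): undefined [%s]\n", x$route, x$flag))
  } else {
    cat(sprintf("CC_max (%s route): %.4f\n", x$route, x$value))
  }
  invisible(x)
}

#' Expected coherence between true rate and N-trial PSTH
#'
#' `gamma^2 = SP / (SP + NP/n)`: the coherence (equivalently the squared
#' noise ceiling, `cc_max_direct()^2`) between the unknown underlying rate
#' and a PSTH averaged over `n` trials, as a function of the signal and
#' noise power. Approaches 1 as `n` grows or the noise vanishes.
#'
#' @param sp signal power (> 0).
#' @param np noise power (>= 0).
#' @param n number of trials averaged (>= 1).
#' @return coherence in `(0, 1]`; undefined (flag `SP_NONPOSITIVE`) for
#'   `sp <= 0`.
#' @export
expected_coherence <- function(sp, np, n) {
  stopifnot(n >= 1, np >= -1e-12)
  if (!is.finite(sp) || sp <= 0) return(undefined_metric("SP_NONPOSITIVE"))
  sp / (sp + np / n)
}

#' Normalized correlation coefficient (closed form)
#'
#' The noise-ceiling-corrected model performance metric:
#' `CC_norm = Cov(y, y_hat) / sqrt(Var(y_hat) * SP)`, with `y` the PSTH and
#' `SP` the signal power of the trial matrix. It equals
#' `cc_abs / cc_max` but needs no resampling: the denominator replaces the
#' PSTH variance in Pearson's correlation with the explainable (signal)
#' part of that variance. A perfect model scores 1 regardless of how noisy
#' the recording is; values below 0 indicate anticorrelation.
#'
#' When the data are so noisy that `SP` is underestimated, the ratio can
#' stray outside `[-1, 1]`; values beyond 1.5 in magnitude additionally get
#' the warning flag `CC_NORM_OUT_OF_RANGE` (symptom of a noise-dominated
#' signal-power estimate — treat with caution).
#'
#' @param trials a [trial_matrix()] (N >= 2).
#' @param yhat predicted rate series of length `T`.
#' @param decomposition optionally a precomputed [signal_power()].
#' @return CC_norm; undefined with flag `SP_NONPOSITIVE` or
#'   `CONSTANT_PREDICTION`.
#' @export
cc_norm <- function(trials, yhat, decomposition = signal_power(trials)) {
  trials <- as_trial_matrix(trials)
  y <- as_numeric_rate(compute_psth(trials))
  yhat <- as_numeric_rate(yhat)
  check_same_length(y, yhat)
  if (var(yhat) == 0) return(undefined_metric("CONSTANT_PREDICTION"))
  if (!decomposition$sp_is_valid) {
    return(undefined_metric("SP_NONPOSITIVE", numerator = cov(y, yhat)))
  }
  out <- cov(y, yhat) / sqrt(var(yhat) * decomposition$sp)
  if (abs(out) > 1.5) attr(out, "flag") <- "CC_NORM_OUT_OF_RANGE"
  out
}

#' Normalized correlation via the split-half route
#'
#' The historical estimator `CC_norm = CC_abs / CC_max`, with `CC_max`
#' obtained by split-half resampling ([split_half_cc()] then
#' [cc_max_from_split()]). Retained to demonstrate its agreement with the
#' closed form [cc_norm()]: the split route converges to the direct route as
#' the number of splits grows, but remains a noisier estimate.
#'
#' @inheritParams cc_norm
#' @inheritParams split_half_cc
#' @return CC_norm estimate; undefined flags from the constituents
#'   (`CCHALF_NONPOSITIVE`, `CONSTANT_PREDICTION`, `CONSTANT_PSTH`)
#'   propagate.
#' @export
cc_norm_via_split <- function(trials, yhat, n_splits = 126, seed = 0) {
  trials <- as_trial_matrix(trials)
  ca <- cc_abs(compute_psth(trials), yhat)
  if (!is.null(metric_flag(ca))) return(ca)
  cm <- cc_max_from_split(split_half_cc(trials, n_splits = n_splits, seed = seed))
  if (!is.null(cm$flag)) return(undefined_metric(cm$flag))
  as.numeric(ca) / cm$value
}
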