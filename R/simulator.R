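#' Specify a synthetic repeated-trial experiment
#'
#' A simulation spec bundles a known time-varying firing-rate function with
#' the trial geometry (number of trials, duration, bin width) and a seed.
#' Passing it to [simulate_trials()] yields Poisson spike counts around that
#' rate — data whose signal power, noise power and noise ceiling are known,
#' so every metric in the package can be validated against ground truth.
#'
#' `rate_fn` is a function of time in seconds returning the instantaneous
#' firing rate in spikes/s; it must be non-negative (rectify inside the
#' function). Helpers [rate_sinusoid()], [rate_constant()] and
#' [rate_filtered_noise()] build common choices.
#'
#' @param rate_fn function(t_seconds) -> spikes/s, vectorized, >= 0.
#' @param n_trials number of repeated presentations `N` (>= 1).
#' @param duration stimulus duration in seconds.
#' @param bin_width bin width in seconds (default 5 ms).
#' @param seed integer seed driving all Poisson draws.
#' @return object of class `sim_spec`.
#' @examples
#' spec <- simulation_spec(rate_sinusoid(20, 15, 2), n_trials = 10,
#'                         duration = 1, seed = 1)
#' sim <- simulate_trials(spec)
#' signal_power(sim$trials)
#' @export
simulation_spec <- function(rate_fn, n_trials, duration, bin_width = 0.005,
                            seed = 0) {
  stopifnot(is.function(rate_fn), n_trials >= 1, duration > 0, bin_width > 0)
  if (floor(duration / bin_width + 1e-9) < 2) {
    stop("duration/bin_width must give at least 2 bins", call. = FALSE)
  }
  structure(list(rate_fn = rate_fn, n_trials = as.integer(n_trials),
                 duration = duration, bin_width = bin_width,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Half-rectified sinusoidal rate function
#'
#' `rate(t) = max(0, mean + amplitude * sin(2 pi f t))` in spikes/s.
#' @param mean_rate mean firing rate, spikes/s.
#' @param amplitude modulation depth, spikes/s.
#' @param frequency modulation frequency, Hz.
#' @return a rate function for [simulation_spec()].
#' @export
rate_sinusoid <- function(mean_rate, amplitude, frequency) {
  force(mean_rate); force(amplitude); force(frequency)
  function(t) pmax(0, mean_rate + amplitude * sin(2 * pi * frequency * t))
}

#' Constant rate function
#' @param rate firing rate in spikes/s (>= 0).
#' @rdname rate_sinusoid
#' @export
rate_constant <- function(rate) {
  stopifnot(rate >= 0)
  function(t) rep(rate, length(t))
}

#' Half-rectified smoothed-noise rate function
#'
#' Gaussian noise on a fine grid, smoothed with a Gaussian kernel of width
#' `tau` and half-rectified — a generic "naturalistic" fluctuating rate.
#' The draw is fixed by `seed`, so the resulting function is deterministic.
#'
#' @param mean_rate,sd_rate mean and standard deviation before
#'   rectification, spikes/s.
#' @param tau smoothing time constant, seconds.
#' @param duration time span covered, seconds.
#' @param seed seed fixing the noise draw.
#' @rdname rate_sinusoid
#' @export
rate_filtered_noise <- function(mean_rate, sd_rate, tau = 0.05,
                                duration = 1, seed = 0) {
  dt <- tau / 10
  grid <- seq(0, duration, by = dt)
  raw <- with_local_seed(seed, rnorm(length(grid)))
  half <- ceiling(3 * tau / dt)
  kern <- dnorm(seq(-half, half) * dt, sd = tau)
  kern <- kern / sum(kern)
  sm <- stats::filter(c(rev(raw[seq_len(half)]), raw, rev(rev(raw)[seq_len(half)])),
                      kern, sides = 2)
  sm <- as.numeric(sm)[half + seq_along(grid)]
  sm <- (sm - mean(sm)) / sd(sm)
  vals <- pmax(0, mean_rate + sd_rate * sm)
  function(t) {
    idx <- pmin(length(grid), pmax(1, round(t / dt) + 1))
    vals[idx]
  }
}

#' Simulate Poisson spike-count trials around a known rate
#'
#' Draws `counts[n, t] ~ Poisson(rate(t_mid) * bin_width)` independently per
#' trial and bin, where `t_mid` is the centre of bin `t`. Each trial uses a
#' deterministic substream derived from the spec seed, so identical specs
#' give bitwise-identical matrices regardless of how many other draws
#' happened in the session.
#'
#' @param spec a [simulation_spec()].
#' @return list with `trials` (a [trial_matrix()]) and `true_rate` (a
#'   [rate_series()] of expected counts per bin — the ground-truth signal).
#' @export
simulate_trials <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n_bins <- floor(spec$duration / spec$bin_width + 1e-9)
  t_mid <- (seq_len(n_bins) - 0.5) * spec$bin_width
  lambda <- spec$rate_fn(t_mid) * spec$bin_width
  if (any(lambda < 0)) stop("rate function returned a negative rate", call. = FALSE)
  counts <- matrix(0L, nrow = spec$n_trials, ncol = n_bins)
  for (n in seq_len(spec$n_trials)) {
    counts[n, ] <- with_local_seed(trial_seed(spec$seed, n),
                                   rpois(n_bins, lambda))
  }
  list(trials = trial_matrix(counts, bin_width = spec$bin_width),
       true_rate = rate_series(lambda, bin_width = spec$bin_width))
}

# per-trial substream seed, kept inside 32-bit integer range
trial_seed <- function(seed, n) {
  as.integer((as.double(seed) + 1000003 * as.double(n)) %% 2147483647)
}

#' The two-sinusoid worked example
#'
#' A simple cell responds with rate `y = 10 + sin(2 pi t)` spikes/s (1 Hz,
#' amplitude 1, mean 10). Two wrong models predict at 2 Hz: model A with
#' amplitude 2 around the correct mean 10, model B with amplitude 1 around a
#' grossly biased mean of 100. Both are orthogonal to `y` (zero covariance),
#' yet model A's prediction error never exceeds 3 spikes/s while model B's
#' never drops below 88 spikes/s — and SPE nevertheless ranks A below B,
#' illustrating why an unbounded-below metric misleads.
#'
#' @param n_points number of samples over one 1-second period (default
#'   100000; the grid covers whole periods so the sinusoids are exactly
#'   orthogonal).
#' @return list of [rate_series()]: `y`, `yhat_A`, `yhat_B` (spikes/s), plus
#'   the time grid `t`.
#' @export
sine_models <- function(n_points = 1e5) {
  if (n_points < 4) stop("need at least 4 grid points", call. = FALSE)
  t <- seq(0, 1, length.out = n_points + 1)[seq_len(n_points)]
  bw <- 1 / n_points
  list(t = t,
       y      = rate_series(10 + sin(2 * pi * t), bin_width = bw),
       yhat_A = rate_series(10 + 2 * sin(2 * pi * 2 * t), bin_width = bw),
       yhat_B = rate_series(100 + sin(2 * pi * 2 * t), bin_width = bw))
}

#' Degrade a prediction with additive white noise
#'
#' Mixes the clean prediction with Gaussian white noise `w` matched to the
#' prediction's mean and standard deviation:
#' `y_hat_alpha = max(0, alpha * w + (1 - alpha) * y_hat)`, negative values
#' rectified to zero. `alpha = 0` returns the prediction untouched;
#' `alpha = 1` is rectified pure noise. Sweeping `alpha` produces a family
#' of predictions of controlled quality for studying how metrics degrade.
#'
#' @param yhat clean predicted [rate_series()].
#' @param alpha mixing level in `[0, 1]`.
#' @param seed seed for the noise draw.
#' @return object of class `degraded_prediction`: list with `values` (a
#'   [rate_series()]), `alpha`, `noise_seed`.
#' @export
degrade_prediction <- function(yhat, alpha, seed = 0) {
  stopifnot(alpha >= 0, alpha <= 1)
  v <- as_numeric_rate(yhat)
  bw <- attr(yhat, "bin_width")
  if (is.null(bw)) bw <- 0.005
  w <- with_local_seed(seed, rnorm(length(v), mean = mean(v), sd = sd(v)))
  out <- pmax(0, alpha * w + (1 - alpha) * v)
  structure(list(values = rate_series(out, bin_width = bw),
                 alpha = alpha, noise_seed = seed),
            class = "degraded_prediction")
}
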