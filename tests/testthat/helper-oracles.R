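# Shared fixtures and independent oracles for the metric routes.

# population-convention moments, for the convention-invariance checks
var_pop <- function(x) mean((x - mean(x))^2)
cov_pop <- function(x, y) mean((x - mean(x)) * (y - mean(y)))

# small random Poisson-ish trial matrix with a reproducible seed
random_trials <- function(seed, n = 6, t = 40, lambda_max = 4) {
  set.seed(seed)
  lam <- runif(t, 0, lambda_max)
  trial_matrix(matrix(rpois(n * t, rep(lam, each = n)), nrow = n))
}

# signal power straight from the averaged-PSTH identity:
# SP = (N * Var(y) - TP) / (N - 1)
sp_from_psth <- function(tm) {
  m <- unclass(tm)
  n <- nrow(m)
  tp <- mean(apply(m, 1, var))
  (n * var(colMeans(m)) - tp) / (n - 1)
}

# 1/CC_max^2 expressed in the raw sums Var(sum_n R_n) and sum_n Var(R_n)
inv_ccmax_sq_rawsums <- function(tm) {
  m <- unclass(tm)
  n <- nrow(m)
  v_sum <- var(colSums(m))
  s_var <- sum(apply(m, 1, var))
  (1 - 1 / n) + (1 - 1 / n) * s_var / (v_sum - s_var)
}

# quick Poisson simulation around a half-rectified sinusoid
quick_sim <- function(seed, n_trials = 20, t_bins = 200, peak = 100) {
  spec <- simulation_spec(rate_sinusoid(0, peak, 2), n_trials = n_trials,
                          duration = t_bins * 0.005, bin_width = 0.005,
                          seed = seed)
  simulate_trials(spec)
}
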