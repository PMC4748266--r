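test_that("total power is the average single-trial variance", {
  expect_equal(total_power(trial_matrix(rbind(c(0, 2), c(2, 0)))), 2)
  expect_equal(total_power(trial_matrix(rbind(c(0, 2), c(0, 2)))), 2)
  const <- trial_matrix(matrix(3L, nrow = 4, ncol = 5))
  expect_equal(total_power(const), 0)
})

test_that("signal power decomposition: known cases and exact TP = SP + NP", {
  d <- signal_power(trial_matrix(rbind(c(0, 2), c(0, 2))))
  expect_equal(d$sp, 2)
  expect_equal(d$np, 0)
  expect_true(d$sp_is_valid)

  # anti-correlated trials: SP = (Var(sum) - sum Var)/(N(N-1)) = (0 - 4)/2
  d2 <- signal_power(trial_matrix(rbind(c(0, 2), c(2, 0))))
  expect_equal(d2$sp, -2)
  expect_equal(d2$np, 4)
  expect_false(d2$sp_is_valid)

  expect_error(signal_power(trial_matrix(c(1, 2, 3))), "2 trials")

  for (seed in 1:10) {
    d <- signal_power(random_trials(seed))
    expect_identical(d$np, d$tp - d$sp)    # NP is exactly the residual power
    expect_equal(d$tp, d$sp + d$np, tolerance = 1e-14)
    expect_gte(d$tp, 0)
  }
})

test_that("the two algebraic routes to signal power agree to 1e-10", {
  for (seed in 1:10) {
    tm <- random_trials(seed, n = sample(2:9, 1), t = sample(10:60, 1))
    d <- signal_power(tm)
    expect_equal(d$sp, sp_from_psth(tm), tolerance = 1e-10)
  }
})

test_that("the signal power estimator is unbiased on Poisson trials", {
  # mean SP over many simulations should approach Var(true expected counts)
  n_sims <- 1000
  sp_v <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    sim <- quick_sim(i, n_trials = 8, t_bins = 50)
    sp_v[i] <- signal_power(sim$trials)$sp
  }
  truth <- var(as.numeric(simulate_trials(
    simulation_spec(rate_sinusoid(0, 100, 2), 2, 50 * 0.005, 0.005, 1)
  )$true_rate))
  se <- sd(sp_v) / sqrt(n_sims)
  expect_lt(abs(mean(sp_v) - truth), 3 * se)
})

test_that("CD rewards exact fits and punishes bias", {
  y <- rate_series(c(1, 3, 2, 5, 4))
  expect_equal(as.numeric(coefficient_of_determination(y, y)), 1)
  expect_equal(as.numeric(coefficient_of_determination(
    rate_series(c(1, 1)), rate_series(c(0, 0)))), 0)

  cds <- sapply(c(0, 0.5, 1, 2), function(b)
    as.numeric(coefficient_of_determination(y, rate_series(as.numeric(y) + b))))
  expect_true(all(diff(cds) < 0))

  z <- rate_series(c(0, 0, 0))
  expect_true(is.na(coefficient_of_determination(z, z)))
  expect_identical(metric_flag(coefficient_of_determination(z, z)),
                   "ZERO_OBSERVATION")
})

test_that("VE ignores bias but reflects residual variance", {
  y <- rate_series(c(1, 3, 2, 5, 4))
  expect_equal(as.numeric(variance_explained(y, y)), 1)
  expect_equal(as.numeric(variance_explained(
    y, rate_series(as.numeric(y) + 7))), 1)
  expect_identical(metric_flag(variance_explained(rate_series(c(2, 2, 2)),
                                                  rate_series(c(1, 2, 3)))),
                   "CONSTANT_PSTH")

  # independent prediction with matched variance: VE approaches -1 in mean
  set.seed(1)
  ve <- replicate(400, {
    a <- rnorm(100); b <- rnorm(100)
    as.numeric(variance_explained(rate_series(a), rate_series(b)))
  })
  expect_lt(abs(mean(ve) + 1), 0.05)
})

test_that("SPE: constant predictions score zero, orthogonal ones -Var/SP", {
  for (seed in 1:5) {
    tm <- random_trials(seed)
    d <- signal_power(tm)
    if (!d$sp_is_valid) next
    for (cst in c(0, 1, 800)) {
      v <- spe(tm, rate_series(rep(cst, ncol(tm))), d)
      expect_identical(as.numeric(v), 0)
    }
  }

  # zero-covariance prediction: SPE = -Var(yhat)/SP exactly
  r <- c(4, 2, 4, 2, 4, 2, 4, 2)
  tm <- trial_matrix(rbind(r, r))       # SP = Var(r), noiseless
  d <- signal_power(tm)
  orth <- c(1, 1, 3, 3, 1, 1, 3, 3)     # cov with r is 0
  expect_equal(cov(r, orth), 0)
  v <- spe(tm, rate_series(orth), d)
  expect_equal(as.numeric(v), -var(orth) / d$sp)
  expect_identical(metric_flag(v), "NEGATIVE_SPE")

  # perfect prediction: SPE = Var(y)/SP (= 1 on noiseless repeats)
  expect_equal(as.numeric(spe(tm, rate_series(r))), var(r) / d$sp)
  expect_equal(as.numeric(spe(tm, rate_series(r))), 1)
})

test_that("SPE difference form and covariance form agree to 1e-10", {
  for (seed in 1:10) {
    tm <- random_trials(seed)
    d <- signal_power(tm)
    if (!d$sp_is_valid) next
    set.seed(seed + 100)
    yhat <- rate_series(pmax(0, as.numeric(compute_psth(tm)) + rnorm(ncol(tm), 0, 0.5)))
    a <- as.numeric(spe(tm, yhat, d))
    b <- as.numeric(spe_covariance_form(compute_psth(tm), yhat, d$sp))
    expect_equal(a, b, tolerance = 1e-10)
  }
})

test_that("covariance-form SPE reproduces the two-bad-models ranking", {
  # orthogonal predictions with Var 2 and 0.5 against SP = 0.5:
  # the larger-variance model scores more negatively (-4 vs -1) even though
  # its pointwise error is smaller
  y <- c(1, -1, 1, -1)
  base <- c(1, 1, -1, -1)               # cov(y, base) = 0
  yh_big <- base * sqrt(2 / var(base))      # Var = 2
  yh_small <- base * sqrt(0.5 / var(base))  # Var = 0.5
  expect_equal(as.numeric(spe_covariance_form(y, yh_big, 0.5)), -4)
  expect_equal(as.numeric(spe_covariance_form(y, yh_small, 0.5)), -1)
  expect_equal(as.numeric(spe_covariance_form(y, rep(5, 4), 0.5)), 0)
})

test_that("metrics are invariant to common rescaling and to the variance convention", {
  tm <- random_trials(7)
  d <- signal_power(tm)
  y <- compute_psth(tm)
  set.seed(8)
  yhat <- rate_series(pmax(0, as.numeric(y) + rnorm(ncol(tm), 0, 0.3)))

  k <- 3L
  tm_k <- trial_matrix(unclass(tm) * k)
  yhat_k <- rate_series(as.numeric(yhat) * k)
  expect_equal(as.numeric(coefficient_of_determination(compute_psth(tm_k), yhat_k)),
               as.numeric(coefficient_of_determination(y, yhat)), tolerance = 1e-12)
  expect_equal(as.numeric(variance_explained(compute_psth(tm_k), yhat_k)),
               as.numeric(variance_explained(y, yhat)), tolerance = 1e-12)
  expect_equal(as.numeric(spe(tm_k, yhat_k)), as.numeric(spe(tm, yhat)),
               tolerance = 1e-12)
  expect_equal(as.numeric(cc_norm(tm_k, yhat_k)), as.numeric(cc_norm(tm, yhat)),
               tolerance = 1e-12)

  # population (/T) convention throughout gives the same VE, SPE, CC metrics
  yv <- as.numeric(y); pv <- as.numeric(yhat)
  ve_pop <- 1 - var_pop(yv - pv) / var_pop(yv)
  expect_equal(ve_pop, as.numeric(variance_explained(y, yhat)), tolerance = 1e-12)
  m <- unclass(tm); n <- nrow(m)
  sp_pop <- (var_pop(colSums(m)) - sum(apply(m, 1, var_pop))) / (n * (n - 1))
  spe_pop <- (2 * cov_pop(yv, pv) - var_pop(pv)) / sp_pop
  expect_equal(spe_pop, as.numeric(spe(tm, yhat)), tolerance = 1e-12)
  ccn_pop <- cov_pop(yv, pv) / sqrt(var_pop(pv) * sp_pop)
  expect_equal(ccn_pop, as.numeric(cc_norm(tm, yhat)), tolerance = 1e-12)
})

test_that("SP <= 0 yields flagged undefined results, never exceptions", {
  tm <- trial_matrix(rbind(c(0, 2), c(2, 0)))
  yhat <- rate_series(c(1, 2))
  v <- spe(tm, yhat)
  expect_true(is.na(v))
  expect_identical(metric_flag(v), "SP_NONPOSITIVE")
  expect_true(is.finite(attr(v, "numerator")))
  v2 <- cc_norm(tm, yhat)
  expect_true(is.na(v2))
  expect_identical(metric_flag(v2), "SP_NONPOSITIVE")
})
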