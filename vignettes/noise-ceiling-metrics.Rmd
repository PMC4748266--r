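---
title: "Scoring neural encoding models against the noise ceiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring neural encoding models against the noise ceiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccnorm)
```

## The statistical model

Everything in this package rests on one assumption about repeated-trial
recordings: the spike counts `R_n(t)` of trial `n` in time bin `t` are the
sum of a deterministic, stimulus-locked rate and additive noise that is
independent across trials and independent of recent stimulus history. The
trial average

$$y(t) = \frac{1}{N}\sum_{n=1}^{N} R_n(t)$$

(the PSTH) is then a noisy estimate of the true underlying rate, converging
to it only as $N \to \infty$. A model prediction $\hat y(t)$ can at best
explain the deterministic part; scoring it against the finite-$N$ PSTH with
CD, VE or a raw correlation mixes model error with irreducible trial noise.

Under that assumption, the total power $TP = \frac1N \sum_n
\mathrm{Var}(R_n)$ (variances taken across time bins) decomposes into signal
power and noise power. The cross-trial estimator

$$SP = \frac{\mathrm{Var}\!\left(\sum_n R_n\right) - \sum_n
\mathrm{Var}(R_n)}{N(N-1)}, \qquad NP = TP - SP$$

is unbiased for the variance of the underlying rate: squaring the sum of
trials makes the cross-trial covariances — which only the stimulus-locked
component contributes — carry the signal, while the per-trial variances
subtract the noise. An algebraically equivalent route goes through the PSTH,
$SP = (N\,\mathrm{Var}(y) - TP)/(N-1)$; the test suite holds the two routes
together to a relative $10^{-10}$.

Two performance metrics are built on $SP$:

* **Signal power explained**
  $SPE = (\mathrm{Var}(y) - \mathrm{Var}(y - \hat y))/SP
       = (2\,\mathrm{Cov}(y,\hat y) - \mathrm{Var}(\hat y))/SP$.
  The covariance form makes its pathology visible: the score rewards
  covariance but *penalizes prediction variance*, so a zero-covariance
  prediction scores $-\mathrm{Var}(\hat y)/SP$ — unboundedly negative as its
  amplitude grows — while every constant prediction, including a "dead
  neuron" predicting zero, scores exactly 0.

* **Normalized correlation**
  $CC_{norm} = \mathrm{Cov}(y,\hat y)\big/\sqrt{\mathrm{Var}(\hat y)\,SP}$,
  Pearson's correlation with the PSTH variance replaced by its explainable
  part. It equals $CC_{abs}/CC_{max}$ with the noise ceiling
  $CC_{max} = \sqrt{SP/(SP + NP/N)}$ — the correlation between the
  $N$-trial PSTH and the true rate implied by the coherence relation
  $\gamma^2 = SP/(SP + NP/N)$. The historical estimate of that ceiling via
  split-half reliability, $CC_{max} = \sqrt{2/(1 + 1/CC_{half})}$, is
  retained (`split_half_cc()`, `cc_max_from_split()`) purely to demonstrate
  agreement with the closed form; `agreement_study()` shows the two routes
  coincide up to resampling error.

When the prediction equals the PSTH itself, $SPE = CC_{norm}^2$ exactly;
`noise_sweep()` shows the two agreeing for good predictions and diverging
sharply — $SPE$ unboundedly negative, $CC_{norm}$ pinned near zero — as a
prediction is degraded toward noise. That divergence, not any single
number, is the reason the package reports both.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `bin_width` | 0.005 | s | 5 ms bins are a common compromise between temporal resolution and counting statistics for cortical spike trains. All metrics are invariant to the unit choice (counts/bin vs spikes/s), so binning only matters through the time resolution itself. |
| `n_splits` | 126 | splits | Random half-splits used when exhaustive enumeration is too costly. 126 keeps a split-half evaluation cheap while holding the resampling noise on `CC_half` to a few percent; exhaustive enumeration kicks in automatically whenever the number of distinct partitions is at most `max(n_splits, 1000)`. |
| `seed` | 0 | — | Every random component (splits, Poisson draws, degradation noise) is seeded; identical seeds give bitwise-identical results. |
| `fisher_z` | `FALSE` | — | `CC_half` aggregates per-split correlations by arithmetic mean, matching the practice the split-half route is meant to reproduce; Fisher-z averaging is available but not the default. |

Variances and covariances use the sample convention (denominator $T-1$)
throughout. The choice is immaterial: every headline metric is a ratio in
which the convention cancels, and the test suite verifies that a consistent
population-convention ($\div T$) implementation gives identical VE, SPE and
CC values.

## Degenerate inputs

The $SP$ estimator is unbiased but noisy; on weakly driven units or with few
trials it can come out zero or negative, in which case $1/SP$ and
$\sqrt{SP}$ are meaningless (or imaginary). The policy is uniform:

* metrics that divide by $SP$ (`spe()`, `cc_norm()`, `cc_max_direct()`)
  return an `NA` carrying the flag `SP_NONPOSITIVE` (plus the raw
  numerator, for diagnostics) rather than a number or an error;
* a constant prediction flags `CONSTANT_PREDICTION` where a correlation is
  requested (SPE is still defined and exactly 0 there — the constant case
  is short-circuited so the zero is exact, not a rounding residue);
* a non-positive `CC_half` flags `CCHALF_NONPOSITIVE`; splits whose
  half-PSTH is constant are dropped and counted;
* a $|CC_{norm}| > 1.5$ is returned but flagged `CC_NORM_OUT_OF_RANGE`,
  the symptom of a noise-dominated $SP$ estimate;
* negative SPE values are never clamped — they are returned with a
  `NEGATIVE_SPE` flag, because the metric's behaviour below zero is
  precisely what needs to be visible.

`evaluate_prediction()` collects all flags into the report, and
`summarize_population()` reports both the raw mean SPE and the mean of
$\max(SPE, 0)$ side by side: a handful of very negative units can drag the
raw mean down for reasons (large prediction variance) that say little about
prediction quality, and neither summary alone is an honest population
figure.

Time-segment exclusion (silent gaps between stimuli and the onset
transients after them) is left to the caller: it is a property of the
experimental design, not of the metrics, and any policy hard-coded here
would be wrong for someone's paradigm.

## What the simulator emulates — and what it does not

`simulate_trials()` draws independent Poisson counts per trial and bin
around a known rate function, the canonical rate-coding noise model: the
noise is additive, stimulus-independent across trials, and has
variance-equals-mean (Fano factor 1) statistics, which the test suite
checks. This is exactly the assumption under which the $SP$/$NP$
decomposition is derived, so simulations provide ground truth for
unbiasedness and recovery tests: the mean of $\widehat{SP}$ over
simulations converges to the variance of the true expected counts, and a
prediction equal to the true rate recovers a mean SPE of 100% and a mean
CC_norm near 1.

Real recordings violate these assumptions in ways the simulator
deliberately does not reproduce: spike-count variance is often
super-Poisson, noise is correlated across time bins and slowly
nonstationary across trials, and refractoriness imposes negative
correlations at short lags. Passing the simulation-based tests therefore
certifies the *estimators and algebra*, not that any particular recording
satisfies the additive-noise model. On real data the practical caveat
stands: when $SP$ is small or its confidence interval wide, $CC_{norm}$
and SPE are unstable and the flags should be taken seriously.

Prediction degradation (`degrade_prediction()`) mixes the clean prediction
with Gaussian white noise matched to the prediction's own mean and standard
deviation, then rectifies at zero. Matching the noise scale to the
prediction keeps the sweep comparable across predictions of different
amplitude; it is a choice (the degradation could equally be scaled to the
data), made once, and only qualitative conclusions — agreement of
$SPE$ with $CC^2_{norm}$ at low noise, divergence at high noise — are drawn
from it.

## Numerical and design choices

* **Half-open bins.** `bin_spikes()` uses $[t_0, t_0 + \Delta)$ bins with
  0-based indices; a spike exactly on a boundary belongs to the later bin.
  A trailing partial bin is dropped with a warning rather than padded,
  since a short bin would distort the variance across bins.
* **Split enumeration.** For even $N$ the $\tbinom{N}{N/2}/2$ unordered
  partitions are enumerated by fixing trial 1 in the first half; for odd
  $N$ halves have sizes $\lfloor N/2\rfloor$ and $\lceil N/2\rceil$.
  Random splits are drawn without duplicates under a local RNG state, so
  calling the function never perturbs the caller's random stream.
* **Per-trial substreams.** Each simulated trial draws from a seed derived
  deterministically from the spec seed, so a trial's counts do not depend
  on how many trials precede it.
* **Route cross-checks as invariants.** The algebraically equivalent
  formulations (two for $SP$, two for SPE, three for $CC_{max}$, two for
  $CC_{norm}$) are all implemented or reconstructed independently in the
  tests and held together at relative $10^{-10}$; the only intentional
  deviation from verbatim algebra is the exact-zero short-circuit for
  constant predictions noted above.
* **Problem sizes.** The stochastic tests run at desk scale chosen for
  tight Monte-Carlo error at interactive runtimes: 20 trials × 200 bins
  for recovery and route-agreement checks, 1000 simulations for the
  perfect-model SPE average (Monte-Carlo standard error ≈ 0.3 percentage
  points, comfortably inside the ±2-point acceptance band), 600–1000
  simulations at 8 trials × 50 bins for the unbiasedness checks.

## Limitations

* Only the single-coherence bound enters; no frequency-resolved coherence
  spectra, mutual-information extrapolation, or confidence intervals on
  $CC_{norm}$ beyond the per-split diagnostics.
* No model fitting: the package scores predictions, it does not produce
  them.
* The spike-table ingestion path handles plain CSV/TSV only — no
  electrophysiology container formats, spike sorting, or stimulus
  handling.
* Population summaries treat units as exchangeable; no hierarchical
  modelling of across-unit variability.
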