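# ccnorm

Noise-ceiling-corrected performance metrics for neural encoding models.

## The problem

Sensory neurons respond variably even to identical stimuli. When a model
predicts a neuron's time-varying firing rate and is scored against the
trial-averaged response (the PSTH, `y(t) = (1/N) Σₙ Rₙ(t)` over `N`
repeats), ordinary accuracy metrics — the coefficient of determination
(CD), the proportion of variance explained (VE), Pearson's correlation
(CC_abs) — conflate two very different things: how good the model is, and
how noisy the neuron is. Even a *perfect* model of the stimulus-locked
response cannot predict the trial-to-trial noise left in a finite-trial
PSTH, so raw scores undersell good models on noisy data.

`ccnorm` implements the two families of metrics that correct for this:

- **Signal power explained (SPE).** The total power of the recording,
  `TP = (1/N) Σₙ Var(Rₙ)`, splits into the stimulus-locked *signal power*

  `SP = (Var(Σₙ Rₙ) − Σₙ Var(Rₙ)) / (N(N−1))`

  and the residual *noise power* `NP = TP − SP`. SPE scores a prediction
  `ŷ` against only the explainable part:

  `SPE = (Var(y) − Var(y−ŷ)) / SP = (2 Cov(y,ŷ) − Var(ŷ)) / SP`.

  A perfect model scores 1 (100%) in expectation — but SPE has no lower
  bound: any prediction uncorrelated with the data scores `−Var(ŷ)/SP`,
  however small its pointwise error, while every constant prediction
  scores exactly 0. Small and negative SPE values are therefore hard to
  interpret.

- **Normalized correlation (CC_norm).** The noise ceiling — the highest
  correlation any model could reach against an `N`-trial PSTH — is
  classically estimated by split-half resampling,
  `CC_max = sqrt(2 / (1 + 1/CC_half))`, averaging `CC_half` over up to
  `C(N, N/2)/2` distinct half-splits (92,378 for `N = 20`). The package
  provides both that route and the closed form that makes the resampling
  unnecessary:

  `CC_max = sqrt(SP / (SP + NP/N))`,  `CC_norm = Cov(y,ŷ) / sqrt(Var(ŷ)·SP)`.

  `CC_norm` equals `CC_abs / CC_max`, is effectively bounded in [−1, 1],
  and for good predictions `CC_norm²` coincides with SPE — while staying
  interpretable where SPE collapses.

Degenerate data are first-class: when the `SP` estimate is non-positive
(noise-dominated recordings, few trials) or a prediction is constant, the
affected metrics come back as explicitly flagged undefined values
(`SP_NONPOSITIVE`, `CONSTANT_PREDICTION`, ...), never as silent `NaN`s or
errors, so population summaries over many units keep running.

A Poisson spike-train simulator with a known ground-truth rate, a
white-noise prediction degrader, and orchestration for the noise-sweep and
route-agreement experiments make every metric verifiable without any
recordings.

## Worked example

Simulate 10 Poisson trials around a known sinusoidal rate (30 ± 20
spikes/s at 2 Hz, 5 ms bins) and evaluate the *true* rate as the
prediction — a perfect model of a noisy neuron:

```r
library(ccnorm)
spec <- simulation_spec(rate_sinusoid(30, 20, 2), n_trials = 10,
                        duration = 0.5, bin_width = 0.005, seed = 3)
sim <- simulate_trials(spec)
evaluate_prediction(sim$trials, sim$true_rate)
#> Model evaluation: 10 trials x 100 bins (bin width 0.005 s)
#>   TP = 0.1586, SP = 0.009396, NP = 0.1492
#>   CD              0.5824
#>   VE              0.2187
#>   SPE             0.5661
#>   CC_abs          0.4678
#>   CC_half         0.2454
#>   CC_max(split)   0.6278
#>   CC_max(direct)  0.6216
#>   CC_norm         0.7526
#>   CC_norm(split)  0.7452
```

Only ~6% of this recording's power is stimulus-locked (`SP/TP`), so even
the ground-truth rate reaches a raw correlation of just 0.47 — but that is
75% of the noise ceiling `CC_max = 0.62`, which `CC_norm` reports
directly. The split-half route (126 random splits here) lands within a
point of the closed form. With more trials or a longer recording both
SPE and CC_norm concentrate around their ideal values of 1.

`write_metric_report(report, "report.json")` serializes all scores, the
power decomposition, and any diagnostic flags as JSON. The same pipeline
is scriptable via `inst/cli/ccnorm.R` with subcommands `evaluate`,
`simulate`, `sweep` and `agreement`.

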