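Package: ccnorm
Title: Noise-Ceiling-Corrected Performance Metrics for Neural Encoding Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how well a model's predicted firing rate matches
    recorded trial-based neural responses while correcting for trial-to-trial
    variability. Implements the decomposition of repeated-trial spike-count
    responses into signal power and noise power, the signal power explained
    (SPE) statistic, the split-half estimator of the maximum attainable
    correlation (CC_max), and the closed-form normalized correlation
    coefficient (CC_norm), together with a Poisson spike-train simulator
    that provides known ground truth for validating every metric.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
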