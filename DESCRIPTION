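Package: bites
Title: Balanced Individual Treatment Effects for Right-Censored Survival Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates individual treatment effects from right-censored
    time-to-event data by training a shared neural representation with
    treatment-specific Cox partial-likelihood heads, while balancing the
    latent distributions of treated and control patients with a Sinkhorn
    divergence (entropically smoothed optimal transport) penalty.
    Includes the linear Cox T-learner and DeepSurv-style baselines,
    Breslow baseline-hazard estimation, median-survival treatment
    recommendation, ground-truth simulation scenarios with potential
    outcomes, and evaluation via time-dependent concordance, precision in
    estimating heterogeneous effects (PEHE), correct-treatment fractions,
    Kaplan-Meier curves and the log-rank test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
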