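Package: poolctrl
Title: Pooled-Control Bayesian Analysis for Multi-Arm Preclinical Screening Trials
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Statistical pipeline for multi-experiment preclinical drug screens
    with a shared control condition, built around the neonatal rat
    hypoxia-ischemia (Vannucci) brain-injury model. Provides a Bayesian linear
    mixed-effects model that borrows non-concurrent pooled controls across
    experiments via an experiment random effect (blocked Gibbs sampler with
    flat or half-Cauchy scale priors), posterior probability-of-efficacy
    summaries with credible intervals, an iterative rank-based permutation
    procedure for excluding outlier litters among control animals, a
    moderate-injury quality-control gate on control-group medians, and a
    synthetic trial generator emulating the experiment/litter/group structure
    for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    coda,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
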