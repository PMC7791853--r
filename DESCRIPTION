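Package: laminitr
Title: Modelling Clinical Improvement from Equine Endocrinopathic Laminitis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying and modelling recovery from
    hyperinsulinaemia-associated laminitis in horses and ponies.
    Implements the Obel lameness grading and the composite Meier
    (modified Obel) 0-12 severity score as executable rubrics, simulates
    longitudinal cohorts of severity scores with horse-level random
    effects, fits the power-exponential decay nonlinear mixed-effects
    model by stochastic approximation EM (SAEM) with importance-sampling
    log-likelihood and AIC model comparison, and provides cohort-level
    summaries: fast/slow improvement partitioning, median trajectories,
    per-sign resolution tables, and Mann-Whitney U group comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
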