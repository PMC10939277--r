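Package: flowparsim
Title: Simulation and Analysis of Self-Motion Biases in Speed Perception
    and Motion Extrapolation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to simulate and analyse visual psychophysics experiments on
    how visually simulated self-motion biases perceived object speed and motion
    extrapolation (time-to-contact judgements). Provides deterministic trial
    kinematics for a laterally moving ball viewed by a translating observer, a
    generative observer model with incomplete flow parsing (a fraction of
    self-motion speed is attributed to the object) and Weber-fraction
    multiplicative noise, a modified PEST adaptive staircase engine for
    two-interval forced-choice speed estimation, maximum-likelihood fitting of
    cumulative-Gaussian psychometric functions (PSE and JND), the confirmatory
    mixed-model statistical pipeline with bootstrap confidence intervals and
    likelihood-ratio tests, two-step simulation-based estimation of
    per-participant accuracy and precision effects, and Monte Carlo power and
    false-positive-rate estimation over the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    lme4,
    stats,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
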