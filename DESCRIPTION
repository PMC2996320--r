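Package: conjointvision
Title: Conjoint-Measurement Analysis of Knowledge of One's Own Visual
    Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools to simulate and analyse a two-phase psychophysical
    experiment probing whether observers know their own retinal
    sensitivity. A synthetic-observer simulator generates 2AFC
    calibration responses from Quick-Weibull sensitivity curves over an
    eccentricity grid and binary choices between eccentricity-contrast
    pairs, optionally driven by distorted subjective sensitivity maps or
    a lexicographic-semiorder rule. The analysis side provides
    maximum-likelihood psychometric fitting, one-up one-down adaptive
    staircases with point-of-subjective-equality estimation, the
    conjoint-measurement test battery (equivalence, transitivity via
    composed log-linear equivalence transformations, dominance with
    beta-distribution intervals), bootstrap confidence intervals, and
    expected-gain loss accounting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
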