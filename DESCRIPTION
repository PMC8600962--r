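Package: progpower
Title: Power and Sample-Size Simulation for Trials Adjusted for Prognostic Baseline Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Monte-Carlo machinery for quantifying how much statistical power a
    randomized two-arm trial gains by adjusting its primary analysis for a
    baseline prognostic score (for example a radiomic or other machine-learning
    prediction of the untreated outcome). Provides synthetic data-generating
    processes for continuous and right-censored survival outcomes, plasmode
    simulation by bootstrap resampling of an observational cohort with an
    injected artificial treatment effect, adjusted and unadjusted analysis
    models (ordinary least squares; Weibull and log-logistic accelerated
    failure time fits with administrative censoring), and power, type-I error
    and minimum-sample-size searches producing sample-size-versus-effect-size
    curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
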