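Package: sfiadapt
Title: Serial Fixed-Interval Timing: Simulation, Start-Time Estimation
    and Adaptation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing operant behaviour on serial fixed-interval
    (sFI) schedules, in which the reinforced interval changes without cue
    across blocks of trials. Provides a generative simulator of sFI sessions
    (block structure drawn without replacement, a scalar-timing agent with a
    tunable duration-updating rule, Poisson press generation), four
    single-trial start-time estimators (first press, first burst of fast
    inter-press intervals, smoothed press-rate doubling over the session
    baseline, and a Bayesian change-point detector on inter-press intervals
    with a Bayes-factor criterion), and block-transition analyses that
    quantify how quickly responding adapts after the interval changes:
    previous-block normalisation, transition direction and magnitude
    classes, adaptation-latency tests, and trial-by-trial correlations of
    start time with interval duration. All results are tidy tibbles; event
    logs round-trip through plain CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
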