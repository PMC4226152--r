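Package: stoppedsums
Title: Frequency-Magnitude Models for Randomly Stopped Sums
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models for randomly stopped sums: totals S = Z_1 + ... + Z_N of a
    random number N of non-negative magnitudes Z, as arise in gaze durations,
    decision times, and cumulative expenditure. Combines a count (frequency)
    model, a positive-magnitude (severity) model, and a generalized linear
    model for the sums whose log-link coefficients are the sums of the
    frequency and magnitude coefficients. Provides a simulation-based
    estimator of the sums distribution with bootstrap coefficient intervals,
    Bayesian hierarchical estimation (two- and three-level, gamma and
    log-normal variants) via JAGS, model diagnostics, and a Monte Carlo
    engine for Type I error and power studies of the three model layers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    coda,
    jsonlite,
    rjags,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
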