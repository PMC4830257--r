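Package: pexcess
Title: Forensic Analysis of p-Value Distributions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting questionable research practices from the
    distribution of reported statistical results. Parses APA-style test
    results (t, F, r, chi-squared, Z), recalculates p-values from test
    statistics and degrees of freedom, and classifies reported-versus-
    recalculated consistency. Provides the Caliper test (an exact binomial
    comparison of p-value frequencies in adjacent narrow bins below .05)
    with yearly trend estimation, a vectorized simulator of two-sample
    t-test studies with optional stopping (data peeking), a chi-square
    estimator of the effect-size distribution on the Fisher-z scale from
    truncated significant p-values, and two excess measures: the
    effect-size-drop measure and the D odds ratio of observed versus
    expected just-significant p-values. A synthetic-corpus generator with
    ground-truth labels supports end-to-end evaluation without access to
    any real literature corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
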