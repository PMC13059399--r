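Package: pvsignal
Title: Disproportionality-Based Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pharmacovigilance pipeline for FAERS-style spontaneous-report
    extracts. Parses dollar-delimited report table sets or a one-row-per-report
    CSV dialect, normalizes drug names, collapses duplicate case versions,
    restricts to a primary-suspect drug over a quarter window, aggregates
    reaction terms at MedDRA-style PT, SOC and SMQ levels, and computes four
    disproportionality statistics on 2x2 contingency tables (reporting odds
    ratio, proportional reporting ratio with Pearson chi-square, Bayesian
    information component, and the multi-item gamma-Poisson shrinker's
    empirical Bayes geometric mean), flagging signals that pass all four
    thresholds. Includes a seeded simulator of FAERS-like report collections
    with injected signals of known strength, descriptive frequency tables,
    and ranked signal output.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
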