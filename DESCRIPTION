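Package: dyadbargain
Title: Analysis of Dyadic Tray-Choice Bargaining Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for trial-level data from face-to-face
    bargaining experiments in which pairs of children choose between an
    equal and an unequal reward tray. Provides validated CSV input/output
    for coded trials, per-dyad and per-group summary measures, exact
    small-sample tests (two-sided binomial, exact Wilcoxon signed-rank),
    a combinatorial oracle for the expected absolute reward difference
    under random role assignment, Monte Carlo randomization tests for
    pure and common tray-choice strategies, theoretical monopoly and
    alternation outcome curves, dyad strategy classification, negotiation
    descriptives, and a seeded synthetic-data generator for calibration
    and strategy-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
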