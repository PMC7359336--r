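Package: magchron
Title: Individual-Level Analysis of Numerical Distance and Size Effects
    in Magnitude Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for trial-level reaction-time data from symbolic
    magnitude classification experiments (deciding whether a single digit
    is smaller or larger than 5): preprocessing with error-rate screening,
    anticipation removal and sequential +/- 3 SD trimming; per-participant
    regression slopes for the numerical distance, size, ratio and SNARC
    effects; an H0 bootstrap that classifies each participant as showing a
    reliable, reverse, or no effect; split-half reliability with
    Spearman-Brown correction; and group-level frequentist and
    default-prior Bayesian inference (JZS t-test and one-way ANOVA Bayes
    factors, exact r x c Fisher tests on prevalence tables). A synthetic
    experiment generator emulates the paradigm with a known ground-truth
    effect structure so the full pipeline can be exercised and validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
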