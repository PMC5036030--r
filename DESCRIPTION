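Package: occumis
Title: Single-Season Occupancy Models with False-Positive Misclassification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, maximum-likelihood fitting, model selection and
    spatial prediction for single-season site-occupancy models of
    detection/non-detection data, including misclassification models that
    estimate a false-positive detection rate (p10) alongside occupancy (psi)
    and detection (p) probabilities on the logit scale. Implements candidate
    set enumeration with two-way interactions, a two-phase conventional-to-
    misclassification selection workflow, AIC ranking with Akaike weights,
    delta-AIC < 2 model averaging, per-cell occurrence prediction over a grid,
    and survey-design summary statistics. Includes a synthetic-data generator
    with known truth for parameter-recovery studies of interview-style
    presence/absence surveys.
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
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
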