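Package: osmofit
Title: Fitness Trade-Offs and Local Adaptation Along Salinity Gradients
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies salinity tolerance and local adaptation from
    dose-response and common-garden experiments on aquatic insects.
    Provides LC50 estimation from binomial logistic fits with delta-method
    and Fieller intervals, common-garden fitness surrogates (adult
    survival, fecundity, oviposition rate, number of immatures), the
    normalized local-adaptation (LA) index and the magnitude of
    maladaptation (MA) with fitness trade-off quadrant classification,
    supporting statistics (one-way ANOVA with Tukey HSD, sequential
    factorial models, Welch's t-test, logistic survival curves,
    Kaplan-Meier estimation), and calibrated synthetic-data generators
    that emulate both experimental designs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
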