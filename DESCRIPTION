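Package: hygrosense
Title: Quantitative Sensory Testing of Skin Wetness Perception
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantitative sensory testing (QST) of
    regional skin wetness perception. Provides normative z-score
    hygrosensory profiling of individual patients with gain/loss
    classification, weighted mean skin temperature processing of
    multi-site thermistor records, two-way mixed-design ANOVA with
    Greenhouse-Geisser sphericity correction and Tukey/Sidak post hoc
    tests, noncentral-F power analysis, and a seeded synthetic-cohort
    generator with injectable hygrosensory-loss participants for
    end-to-end validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
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
    jsonlite,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
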