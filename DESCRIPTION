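Package: frtnorms
Title: Normative Scoring, Demographic Adjustment and Equivalent Scores
    for the False Recognition Test
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computational stack for the False Recognition Test (FRT), a
    DRM-paradigm neuropsychological instrument with six subscores (free
    recall, recognition, failed recognition, semantic / non-semantic /
    total false memory). Provides item-level scoring with structural
    validation, demographic adjustment of raw scores via published
    regression formulas on transformed age, education and sex,
    nonparametric one-sided tolerance-limit ranks and five-level
    Equivalent Score banding, age-by-education correction grids with
    extrapolation flags, a calibrated synthetic normative-cohort
    generator for testing every pipeline stage without the study's raw
    data, and a reproducible command-line pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
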