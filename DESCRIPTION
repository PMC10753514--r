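Package: tbmethods
Title: Body-Temperature Measurement Methods and Resting Metabolic Rate in Small Birds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for overnight flow-through respirometry and
    continuous body-temperature recording in small birds, built to compare
    measurement methods that differ in invasiveness (intraperitoneal and
    subcutaneous PIT tags, cloacal and cutaneous thermocouples, and
    un-instrumented controls). Includes a seeded synthetic-data generator for
    multiplexed stop-flow respirometry and per-sensor temperature streams;
    gas-exchange equations with mathematical water-vapour scrubbing and
    baseline drift correction; linear sensor calibration; temperature quality
    control (misread-spike removal, recording-range enforcement, rounding and
    1-min binning); resting metabolic rate extraction via the most-stable
    2-min-window rule with time-matched body temperature; heterothermy
    variability indices (coefficient of variation and the consecutive
    disparity index); and the inferential layer (heteroscedastic linear mixed
    models with AICc selection, Wald chi-square tests, estimated marginal
    means with Bonferroni-corrected pairwise contrasts, Welch ANOVA with
    Games-Howell post hoc tests, and group-balance checks).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    nlme,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    car,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
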