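Package: dbsbridge
Title: Bioanalytical Method Validation and Dried Blood Spot to Plasma
    Bridging for Therapeutic Drug Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for regulated LC-MS/MS bioanalytical method
    validation and for bridging dried blood spot (DBS) measurements to plasma
    concentrations in therapeutic drug monitoring. Implements weighted linear
    calibration with formal weighting-factor selection (F-test for
    heteroscedasticity, sum of squares, AIC, sum of absolute percent relative
    error), EMA/FDA accuracy-precision acceptance rules, recovery and
    IS-normalized matrix factor computations, hematocrit-effect assessment,
    conversion-factor estimation from paired plasma/DBS samples, and a full
    method-agreement suite: Passing-Bablok regression with cusum linearity
    test, Bland-Altman analysis, Lin's concordance correlation coefficient,
    the percent-difference rule, and incurred sample reanalysis. Includes
    seeded synthetic-data generators emulating common validation study
    designs so every pipeline stage is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
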