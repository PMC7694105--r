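Package: somatoBIA
Title: Heath-Carter Somatotype Assessment Integrated with Bioelectrical
    Impedance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying the Heath-Carter anthropometric somatotype
    in athletes and for replacing part of the anthropometric measurement set
    with 50 kHz whole-body bioelectrical impedance analysis (BIA). Provides a
    reference Heath-Carter engine (endomorphy, mesomorphy, ectomorphy,
    thirteen-category classification, somatochart projection), BIA-derived
    body composition (phase angle, bioimpedance index, athlete-specific
    fat-free mass), reduced-measurement somatotype prediction equations for
    elite male soccer players, the full equation-development machinery
    (stratified splitting, stepwise ordinary least squares with variance
    inflation screening, residual diagnostics), cross-validation agreement
    statistics (pure error, Lin's concordance correlation coefficient,
    Bland-Altman limits of agreement), and a synthetic-cohort generator with
    internally consistent anthropometry and bioimpedance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
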