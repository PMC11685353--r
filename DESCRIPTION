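Package: iciefval
Title: Method Validation Toolkit for Imaged Capillary Isoelectric Focusing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and statistical validation of imaged capillary
    isoelectric focusing (iCIEF) separations of peptides. Provides
    electropherogram peak detection and integration, pixel-to-pI mapping,
    electrophoretic resolution, repeatability and intermediate-precision
    summaries, ordinary-least-squares calibration with a complete
    regression-assumption battery (leave-one-out influence diagnostics
    with an all-thresholds outlier rule, moment-based and bootstrap
    normality assessment, Breusch-Pagan heteroscedasticity test,
    Durbin-Watson autocorrelation check with exact Imhof bounds),
    Mandel fitting and lack-of-fit linearity tests with stepwise
    elimination of the highest calibration level, inter-day slope
    comparison by pooled and Welch t-tests, detection and quantification
    limits by the signal-to-noise and calibration-slope approaches, and
    sequence-based isoelectric-point prediction under pluggable pKa sets.
    A seeded synthetic-data generator emulates traces and calibration
    series with injectable pathologies so every stage is testable against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    jsonlite,
    yaml,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    boot,
    withr
Config/testthat/edition: 3
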