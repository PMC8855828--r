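Package: ezprog
Title: Photoreceptor Degeneration and Ellipsoid Zone Loss Progression in
    ABCA4 Retinopathy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for quantifying photoreceptor degeneration
    in ABCA4-associated (Stargardt) retinopathy from en face optical
    coherence tomography layer thickness maps. Provides ellipsoid-zone
    (EZ) loss quantification from outer-segment maps (map thresholding and
    the B-scan-wise Riemann-sum grading procedure with break-forgiveness
    rules), normative z-score standardization, contour-band feature
    extraction at fixed distances from the EZ-loss boundary, ETDRS-grid
    subfield summaries, Box-Cox and square-root mixed-model progression
    statistics, per-eye imputation of the age of criterion EZ-loss, and an
    additive allele-severity genotype model with patient-wise
    cross-validation. A synthetic-data generator emulates the longitudinal
    study design so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    lmerTest,
    jsonlite,
    rlang,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
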