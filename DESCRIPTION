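Package: pathsem
Title: Latent-Variable Pathway Analysis of Life-Course Factors, Brain
    Pathology, and Cognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage latent-variable mediation analysis for clinical
    cohort studies of cognitive ageing.  Stage one fits graded response
    models (IRT) to ordinal social and lifestyle items and extracts
    standardized expected-a-posteriori trait scores.  Stage two fits a
    structural equation model by full-information maximum likelihood in
    which the trait scores, together with age, sex, and APOE-e4 status,
    act on a latent cognition factor directly and through three latent
    pathology mediators (small vessel disease, AD pathology,
    neurodegeneration), and decomposes the associations into direct,
    indirect, and total standardized effects with delta-method standard
    errors.  Includes a calibrated synthetic-cohort generator with
    modality-block missing-at-random missingness so that every stage is
    testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    statmod,
    jsonlite,
    yaml
Suggests:
    numDeriv,
    mvtnorm,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
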