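Package: vfnoise
Title: Visual Field Denoising and Weighted Progression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for reducing measurement noise in Humphrey 24-2
    visual fields with a variational autoencoder and for exploiting the
    reconstruction error in glaucoma progression analysis. Provides a
    data model for 52-point total-deviation fields, a synthetic
    longitudinal cohort generator with spatially structured defects and
    sensitivity-dependent test-retest noise, a trainable variational
    autoencoder for tabular field data, inverse-reconstruction-error
    weighted mean-total-deviation trend analysis, binomial pointwise
    linear regression, and an evaluation framework (consistency
    proportions, prediction errors, Kaplan-Meier time to detection).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, survival
Suggests: testthat (>= 3.0.0), yaml, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
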