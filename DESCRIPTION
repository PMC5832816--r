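Package: invermass
Title: Biovolume and Biomass Estimation for Small Invertebrates from
    Silhouette Images and Linear Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates body volume and individual mass of small
    invertebrates (length scales of micrometres to millimetres) from 2D
    binary silhouettes and simple linear measurements. Implements the
    flat-section method (ventral area times mean dorso-ventral thickness),
    a solid-of-revolution method that integrates one-pixel-wide circular
    slices of a Feret-aligned silhouette, a composite method for complex
    morphologies partitioned into flat and subcircular parts, cube-law
    scaling of enlarged clay models, and classical ellipsoid/cylinder
    geometric approximations. Includes focus-drive thickness calibration,
    tissue-density estimation from mass/displacement trials, volume to
    mass conversion, and the validation statistics used to compare
    estimators (one-sample t-tests with Bonferroni correction, linear
    mixed-effect method comparison, overestimation ratios). A synthetic
    shape generator provides silhouettes and populations with analytically
    known volumes so every estimator can be tested without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    grDevices,
    lme4,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
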