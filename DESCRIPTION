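Package: uvcover
Title: Quantification of Sun-Protection Coverage from UV Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for quantifying how completely a sun-protection product
    (sunscreen or SPF moisturiser) has been applied to the face, from
    UV-reflectance photographs in which applied product appears dark.
    Facial regions (face, eyelids, medial canthi) are derived from 68-point
    facial landmarks; a per-participant threshold calibrated on the bare-skin
    baseline image classifies each pixel as covered or uncovered; per-region
    percent-missed metrics and a binary medial-canthus outcome feed a
    repeated-measures statistical battery (normality-gated paired
    comparisons, repeated-measures ANOVA, Sidak-adjusted subgroup contrasts,
    two-factor ANCOVA with an age covariate, order-effect checks,
    dose-response regression). A synthetic image and population generator
    with known ground truth makes the whole analysis runnable and testable
    without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    MASS,
    car,
    jsonlite,
    nortest,
    png,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
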