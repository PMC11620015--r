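Package: ccfdgrid
Title: Grid-Based Quantification and Repeatability of Choriocapillaris
    Flow Deficits from OCT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies choriocapillaris flow-deficit percentages (CCFD%)
    on en-face swept-source OCT angiography images: slab extraction from
    volumetric scans, structure-based signal-attenuation compensation,
    fuzzy C-means global thresholding, greatest-linear-dimension size
    filtering, lesion exclusion masks, rigid registration of repeat scans
    on retinal-vasculature images, integrated cross-scan masks, and
    CCFD% measurement in fovea-centered circles and a 74-pixel box grid.
    Includes the companion repeatability statistics (nested
    variance-component models, intraclass correlation with parametric
    bootstrap intervals, 95% minimal detectable change, Tukey-adjusted
    group contrasts) and an MDC95-based longitudinal change test, plus a
    synthetic-eye generator with known ground truth for end-to-end
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
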