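Package: thyrotherm
Title: Bioheat Simulation and Thermographic Screening of Thyroid Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing whether malignant thyroid nodules are
    detectable from skin-surface temperature. Implements a steady-state
    Pennes bioheat solver on a layered two-dimensional neck cross-section
    (skin, fat, muscle, thyroid gland, elliptic nodule, insulated trachea)
    with a closed-form multilayer verification oracle, profile and
    size-by-fat-thickness sweep utilities, and an infrared-thermogram
    screening pipeline based on the contralateral asymmetry parameter:
    grey-level ROI mapping, geometric-centre mirror axis, asymmetry map,
    thresholding, morphological opening, candidate extraction,
    crop/resize/normalisation, class-specific data augmentation with exact
    count bookkeeping, a synthetic-thermogram generator and a classifier
    evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    EBImage,
    jsonlite,
    data.table,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
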