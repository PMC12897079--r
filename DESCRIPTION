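Package: lesionroi
Title: Segmentation-Guided ROI Preprocessing and Evaluation for Jaw
    Lesion Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how segmentation-guided region-of-interest
    (ROI) preprocessing affects machine-learning differentiation of
    ameloblastoma (AME) from odontogenic keratocyst (OKC) on volumetric
    axial slices. Provides a synthetic phantom cohort generator with
    aligned lesion masks, mask-driven slice selection and four ROI input
    variants (original slice, bounding-box crop, precise segmentation,
    moderately expanded margin), mode-adaptive patient-centric sampling
    (MAPS), a compact convolutional classifier backend with a two-phase
    warm-up/cosine learning-rate schedule, patient-level cross-validation
    without data leakage, slice- and patient-level metrics with soft
    voting, DeLong's test for correlated ROC curves, Grad-CAM attention
    maps and per-patient confidence-curve analysis.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    EBImage,
    jsonlite,
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
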