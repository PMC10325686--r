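Package: scarCCT
Title: Myocardial Scar Detection from Early Contrast-Enhanced Cardiac CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for detecting myocardial fibrosis on early
    contrast-enhanced cardiac CT short-axis volumes: active-contour-style
    myocardium segmentation, AHA 16-segment sectorization, scar labeling from
    late-phase tracings via an enhanced-area-fraction threshold, a compact
    convolutional neural network classifier trained with class-balanced
    undersampling and patient-wise cross-validation, and segment-level
    agreement statistics (bull's-eye maps, Cohen's kappa). Ships a seeded
    synthetic phantom generator producing paired early/late volumes with
    ground-truth myocardium and scar masks, so the full pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
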