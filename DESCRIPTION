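Package: idhconf
Title: Confidence-Informed IDH Classification from Voxel-Wise Tumor Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns per-fold voxel-wise two-class tumor label maps (IDH-mutant
    vs IDH-wildtype voxels) into subject-level IDH calls by per-voxel fold
    ensembling and majority voting, derives the wildtype voxel fraction, and
    calibrates it into confidence scores with logistic regression and
    Bayesian logistic regression under zero-mean Gaussian priors (informative
    N(0,1) and non-informative N(0,1000)). Calibration quality is evaluated
    with the Brier score and standard classification metrics under a
    two-stage held-out protocol (fit on one cohort, score a disjoint one).
    Includes a seeded synthetic cohort generator that reproduces the bimodal
    wildtype-fraction structure of segmentation-network outputs so the whole
    pipeline is testable without images or a trained network.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
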