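Package: synthecv
Title: Automated Synthetic Extracellular Volume Quantification from Cardiac T1 Maps
Version: 0.1.0
Authors@R:
    person("synthecv", "developers", email = "synthecv@example.org", role = c("aut", "cre"))
Description: A fully automated, blood-draw-free pipeline for myocardial
    extracellular volume (ECV) quantification from paired native and
    post-contrast short-axis cardiac T1 maps: segmentation of myocardium and
    blood pools via pluggable backends, measurement-mask refinement (3x3
    morphological erosion and Otsu separation of papillary muscles from the
    blood pool), median T1 extraction, synthetic-hematocrit regression from
    native blood-pool R1, conventional and synthetic ECV computation with
    threshold classification, and the full method-agreement statistics suite
    (Bland-Altman, Pearson, paired t, McNemar, concordance, ICC, Dice,
    Hausdorff). Ships a digital short-axis phantom generator with known
    ground-truth geometry, hematocrit and ECV so every stage is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
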