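Package: axialposture
Title: Markerless Measurement of Axial Postural Abnormalities from Single Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Augments 2D human-pose keypoints (BODY25 dialect) from a single
    RGB photograph with the clinical trunk landmarks C7, L5, MA and FC,
    extracting the subject silhouette with a seeded iterative graph-cut
    segmentation where the landmark lies on the body contour. From the
    augmented landmarks it measures the three axial postural abnormalities
    seen in Parkinsonism - Pisa syndrome (lateral trunk flexion), lumbar and
    thoracic camptocormia (anterior trunk flexion) - as external angles, and
    classifies them against the consensus cut-offs (10, 30 and 45 degrees).
    Includes a Pearson-correlation robustness analysis of measures and
    measurement errors against subject and image covariates, and a synthetic
    mannequin generator with closed-form ground-truth landmarks and angles
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    EBImage,
    png,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jpeg,
    optparse
Config/testthat/edition: 3
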