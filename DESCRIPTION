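Package: lesionwise
Title: Lesion-Wise Evaluation of Automated Brain Metastasis Contours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Stratified, lesion-wise evaluation of automated brain-metastasis
    segmentations against physician ground-truth contours, as used in
    stereotactic-radiosurgery contour quality assurance. Implements
    centroid-containment detection matching, lesion-wise Dice similarity,
    average (symmetric) Hausdorff surface distance in millimetres and as a
    percentage of lesion size, false-positive counting, sensitivity
    stratified by effective lesion diameter, and Kruskal-Wallis comparisons
    of performance metrics across demographic and clinical strata. Includes
    readers and writers for planar structure-set contours (a JSON dialect
    and DICOM RT Structure Sets) and NIfTI label volumes, a contour
    rasterizer, and a calibrated synthetic-cohort simulator with a known
    detection and boundary-error model for end-to-end validation and
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
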