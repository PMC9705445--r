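Package: diaphragmr
Title: Diaphragm Motion and Curvature Quantification from Breath-Hold Lung MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies diaphragmatic motion and curvature from paired
    end-expiration/end-inspiration 3D lung segmentations, as used to monitor
    respiratory muscle involvement in Pompe disease. Computes eight
    inspiration/expiration ratio outcomes (lung volume, diaphragm-displaced
    volume, sagittal lung area, cranial-caudal and anterior-posterior extents,
    their quotient, and diaphragm dome height and area), matches sagittal
    levels across longitudinal visits by exhaustive integer-shift Dice
    registration, and runs the cohort statistics (rank-sum and chi-square
    comparisons, change scores, treatment-duration and weakness subgroups,
    deterioration/improvement classification). Includes a parametric thorax
    phantom with closed-form ground truth for every outcome and a cohort
    simulator with controlled one-year drift for validation.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
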