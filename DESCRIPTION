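Package: gasdose
Title: Dosimetric Impact of Gastrointestinal Gas Pockets in Adaptive
    MR-Guided Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for quantifying how gastrointestinal gas
    pockets perturb dose distributions in online adaptive MR-guided
    radiotherapy. Estimates a gastrointestinal-gas relative electron
    density (GIGED) from CT Hounsfield statistics and a scanner
    calibration curve, compares density-override plan triplets
    (air / water / GIGED) with 2-D gamma analysis on the orthogonal
    planes through the target centroid, extracts DVH metrics, computes
    the Active Gas Volume (AGV) predictor, and runs the cohort-level
    GPR-versus-AGV correlation and threshold analysis. Ships a synthetic
    abdominal phantom generator and a declared toy dose engine with an
    electron-return-effect-like interface perturbation so the whole
    pipeline is testable without clinical data, plus minimal DICOM-RT
    readers and writers (CT, RTSTRUCT, RTDOSE).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
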