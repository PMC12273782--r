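Package: tbi3d
Title: Layer-by-Layer 3D Quantification of Traumatic Brain Injury Pathology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Whole-brain 3D pathology quantification for controlled cortical
    impact traumatic brain injury imaged by light-sheet microscopy of cleared
    tissue. Segments the lesion cavity by mirrored-hemisphere subtraction,
    builds conformal depth layers emanating from the lesion boundary, and
    quantifies the vascular network (Frangi vesselness segmentation,
    skeleton-based length and volume), tissue hypoxia, and macromolecule
    extravasation per layer, with per-brain contralateral background
    thresholding. Includes the accompanying group statistics (IQR outlier
    removal, one-way ANOVA with Fisher's LSD) and delta-delta-Ct qPCR fold
    changes, plus a ground-truthed synthetic brain phantom generator so every
    stage is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
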