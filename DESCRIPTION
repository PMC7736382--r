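Package: lymphseg
Title: Automated Segmentation and Quantification of FDG-Avid Lymphoma on PET/CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated detection, segmentation and quantification of
    FDG-avid lymphoma on co-registered PET/CT volumes. Provides threshold-based
    reference segmentation inside physician-style template regions (union of
    SUV > 2.5 and 40% of per-region SUVmax), an ensemble of multi-resolution
    3D patch convolutional neural networks trained to replicate those
    references, SUV/HU-based post-processing (per-component threshold
    refinement, ensemble intersection, bone exclusion), extraction of the five
    prognostic PET metrics (SUVmax, metabolic tumor volume, total lesion
    glycolysis, surface-area-to-volume ratio, lesion dissemination), and a
    complete evaluation protocol (Dice/sensitivity/PPV, probability-threshold
    sweeps, Pearson correlation and relative percent difference of features,
    median-dichotomized subgroup analysis). A synthetic PET/CT phantom
    generator emulates multi-lesion disease, benign hot structures and bone so
    the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
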