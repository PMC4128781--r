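Package: petmc
Title: Retrospective Movement Correction and Kinetic Quantification for
    Dynamic Brain PET/CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated retrospective image-based movement correction for
    dynamic brain PET/CT studies: head/background CT segmentation, rigid
    CT-to-PET registration by normalized mutual information, inter-frame
    PET registration by normalized cross-correlation, per-frame
    attenuation-weighted OSEM re-reconstruction with the moved CT, and
    realignment of all frames to a reference frame.  Includes a digital
    brain phantom with two-tissue-compartment tracer kinetics and a
    parallel-beam emission-scan simulator so the whole pipeline can be
    validated end-to-end without scanner data, plus downstream
    quantification: region time-activity curves, image-derived input
    functions, Logan DVR and Patlak Ki graphical analysis, and parametric
    images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
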