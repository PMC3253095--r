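Package: trialfmri
Title: Trial-Based Preprocessing and Evaluation for Awake Nonhuman-Primate fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Preprocessing toolkit for trial-structured functional MRI
    acquired from awake nonhuman primates at high field, where animal
    movement between trials causes segmented-EPI ghosting, apparent
    phase-direction shifts of the brain, and between-trial image
    distortion. Provides per-volume quality control (N/2 ghost-ratio and
    centre-of-mass statistics) with semi-automatic trial rejection and
    concatenation of the surviving trial epochs; a 2-step realignment
    combining within-trial single-axis registration with a per-trial
    12-parameter affine, applied in a single reslice; high-pass filtering
    of concatenated series after linear interpolation across the removed
    epochs; radially weighted adaptive brain extraction; and an ordinary
    least squares GLM harness that compares five analysis strategies by
    the proportion of suprathreshold voxels. A seeded simulator generates
    sessions with known ground truth (activation, motion, artefacts) so
    every stage is testable without scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
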