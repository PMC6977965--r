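Package: reachenc
Title: Poisson Encoding Models of Whole-Arm Reaching Kinematics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for comparing Poisson
    generalized linear encoding models of somatosensory cortical activity
    during planar reaching. Generates trial-structured two-link-arm
    kinematics with ground-truth Poisson neurons, fits hand-only, whole-arm
    and related covariate-set models under repeated k-fold cross-validation,
    and evaluates them with deviance pseudo-R2, corrected resampled t-tests,
    bootstrap preferred directions, circular VAF of preferred-direction
    shifts, and LDA separability indices for active versus passive
    movements.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
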