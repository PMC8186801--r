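Package: sfci
Title: Structural and Functional Connectivity Index for Longitudinal
    Neuroimaging of Multiple Sclerosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes a pathway-based composite biomarker of structural and
    functional brain connectivity (the SFCI) from co-registered MRI volumes.
    Provides seed-based resting-state functional connectivity (correlation,
    t-conversion, whole-brain z-normalisation), diffusion-tensor scalar maps
    with track-probability-weighted pathway averages (radial diffusivity),
    normative z-scoring and the hemisphere-minimum composite metric, cohort
    quality control with motion gating and exclusion accounting, longitudinal
    mixed-effects slope estimation with likelihood-ratio testing and false
    discovery rate adjustment, and a synthetic-cohort simulator with ROC/AUC
    evaluation of progression detection as a function of the number of study
    time points.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    lme4,
    stats,
    utils,
    graphics
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
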