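Package: shrf
Title: Subject-Specific Hemodynamic Response Functions for Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis of task fMRI with subject-specific
    hemodynamic response functions (sHRF). Generates synthetic cohorts with
    age-graded vascular risk indicators, event-related designs, and BOLD runs
    with AR(1), drift, and spike noise; estimates each subject's HRF from a
    sensory (checkerboard) run by finite impulse response (FIR) deconvolution;
    computes HRF shape metrics (peak, latency, FWHM, AUC) and Cronbach-alpha
    reliability; fits first-level GLMs for a memory-encoding task under either
    the canonical double-gamma basis with temporal and dispersion derivatives
    or the substituted sHRF; scores vascular risk by exploratory factor
    analysis with direct oblimin rotation and Horn's parallel analysis; and
    performs group-level inference (age-by-risk regressions, mixed ANCOVA
    over analysis type, paired t-maps with cluster-extent thresholding).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
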