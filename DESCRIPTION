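Package: lutadose
Title: Hybrid Planar-SPECT Dosimetry and PET-Based Dose Prediction for
    Lu-177 Radionuclide Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative internal dosimetry of Lu-177 peptide
    receptor radionuclide therapy and its relationship to pre-therapeutic
    Ga-68 PET imaging.  Provides digital sphere-phantom and patient-cohort
    generators with known ground truth, partial-volume recovery-coefficient
    models (volume-only and background-aware) with nonlinear least-squares
    calibration, PET/SPECT activity-concentration quantification (AC/IA and
    SUV), hybrid planar-SPECT time-activity fitting with analytical
    absorbed-dose integration, prediction of Lu-177 tumour absorbed doses
    from Ga-68 activity concentrations using grade-specific population
    effective half-lives, and the accompanying statistical battery
    (weighted and repeated-measures correlations, leave-one-out stability
    intervals, and log-ratio Bland-Altman agreement).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
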