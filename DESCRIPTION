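Package: sprct
Title: Stopping-Power-Ratio Prediction and Range Evaluation for Ion-Beam
    Therapy CT Workflows
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting proton, helium and carbon-ion stopping-power
    ratios (SPR) from CT images and for quantifying the dosimetric impact of the
    imaging chain. Implements the dual-layer spectral CT (DLCT) route (electron
    density and effective atomic number to SPR via the Bethe formula with a
    parametric effective-atomic-number-to-mean-excitation-energy model) and the
    single-energy CT (SECT) route (two-parameter stoichiometric calibration and
    piecewise-linear Hounsfield look-up tables), together with a synthetic
    labeled head phantom and scanner simulator, water-equivalent path-length ray
    tracing with analytical Bragg-peak and spread-out-Bragg-peak depth-dose
    models, distal R90/R80 range-shift extraction, region-of-interest SPR
    statistics with paired tests, local 3D gamma analysis, dose-volume-histogram
    metrics, and a config-driven synthetic cohort study pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
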