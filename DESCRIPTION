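Package: syncfluor
Title: First-Derivative Synchronous Fluorescence Spectrofluorimetry for
    Binary Drug Mixtures
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies two spectrally overlapped fluorophores (modelled on
    the co-formulated drugs atorvastatin and aspirin) by constant
    delta-lambda synchronous fluorescence scanning followed by
    Savitzky-Golay first-derivative amplitude measurement at zero-crossing
    wavelengths. Provides an excitation-emission-matrix simulator with
    Gaussian band models and calibrated replicate noise, spectra and
    sample-sheet I/O, automatic measurement-wavelength and delta-lambda
    selection, univariate calibration with inverse prediction, laboratory
    mixture, standard-addition and tablet-assay workflows, and the full
    ICH Q2 validation battery (linearity, LOD/LOQ, accuracy, precision,
    robustness, two-method t/F comparison).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'fluorophores.R'
    'simulate.R'
    'panels.R'
    'io.R'
    'config.R'
    'syncspec.R'
    'derivative.R'
    'calibration.R'
    'scan.R'
    'workflows.R'
    'validation.R'
    'report.R'
    'demo.R'
    'cli.R'
    'syncfluor-package.R'
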