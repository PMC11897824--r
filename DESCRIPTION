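Package: spectroxy
Title: Tissue Oximetry from Diffuse Reflectance Spectra During Machine Perfusion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates tissue oxygen saturation (StO2) from broadband
    reflectance spectra acquired on perfused organs. Reflectance records are
    converted to inferred absorption spectra, a modified Beer-Lambert model
    combining oxygenated and deoxygenated haemoglobin extinction spectra with
    a polynomial background is fitted by bound-constrained least squares, and
    StO2 is reported as the ratio of the fitted haemoglobin amplitudes.
    Includes per-site aggregation of hand-held probe measurements, median
    smoothing of continuous StO2 time series, pump step-down profile analysis,
    detection of abrupt synchronized perfusion drops against a blood-flow
    index, quality flagging of ambient-light and probe-slip artifacts, and a
    seeded synthetic-data generator for perfusion scenarios (rejection,
    thrombosis, haemorrhage, control) so the full pipeline is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'chromophores.R'
    'spectra-io.R'
    'preprocess.R'
    'hbfit.R'
    'timeseries.R'
    'synthetic.R'
    'pipeline.R'
    'spectroxy-package.R'
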