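Package: hybridphase
Title: Early Detection of Hemodynamic Responses with Hybrid EEG-fNIRS
    Vector-Phase Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for early, single-trial detection of cortical hemodynamic
    responses by fusing electroencephalography (EEG) with functional
    near-infrared spectroscopy (fNIRS).  Implements the modified vector-phase
    diagram in the oxy-/deoxy-hemoglobin plane with a resting-state threshold
    circle and an EEG-band-power-triggered inner circle, modified
    Beer-Lambert-law conversion of dual-wavelength intensities, Butterworth
    band filtering, a two-gamma canonical hemodynamic response model and its
    boxcar-designed convolution, robust-regression t-statistic activation
    mapping, a linear-discriminant baseline classifier, and a seeded synthetic
    dual-modality session generator so the entire pipeline can be exercised
    and validated without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    data.table,
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
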