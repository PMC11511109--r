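Package: ppginv
Title: Detection and Quantification of Photoplethysmographic Signal Inversion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for detecting and quantifying inversion of reflectance
    photoplethysmographic (PPG) pulse waveforms, an anomaly in which reflected
    light intensity rises instead of falls during systole. Implements a
    two-layer per-pulse classifier (systole/diastole symmetry of the first
    derivative, and a law-of-cosines sharpness triangulation), the recording
    level inversion statistics built on it (mean pulse label, degree of
    inversion, and occurrence of inversion across a measurement grid), noise
    and layer-disagreement flagging, a zero-phase preprocessing chain
    (negation, baseline high-pass, Savitzky-Golay smoothing), and a seeded
    synthetic multi-wavelength PPG generator with per-beat polarity ground
    truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
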