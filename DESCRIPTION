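Package: pwvalidr
Title: Validation of Noninvasive Pulse Wave Velocity Measurement Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical and procedural toolkit for technical validation
    studies of noninvasive arterial pulse wave velocity (PWV) devices.
    Implements the tolerable-error probability model for test-minus-reference
    differences (normal model, 85% two-sided bound), device grading
    (good/acceptable/fail at 1.0 and 1.5 m/s), acceptable-SD cutoff tables,
    binomial sample-size calculus, simultaneous and sequential measurement
    pairing, Bland-Altman agreement analysis with stratification, test-retest
    precision, participant eligibility and cohort-composition checking,
    pressure-waveform foot detection (intersecting tangent and diastole
    patching) with transit-time PWV computation, and a synthetic
    validation-study simulator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
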