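Package: cgmerr
Title: Error Modelling and Identification for Factory-Calibrated
    Continuous Glucose Monitoring Sensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and identify the measurement error of
    factory-calibrated continuous glucose monitoring (CGM) sensors over a
    10-day wear period.  The error model dissects the discrepancy between
    blood glucose and CGM readings into three components: first-order
    plasma-to-interstitium diffusion kinetics, a slowly varying
    calibration error (time-dependent gain and offset), and autoregressive
    measurement noise.  The package provides a forward simulator of CGM
    traces, Tikhonov-regularised smoothing of sparse reference samples,
    two-step and single-step constrained nonlinear least-squares
    identification of all model parameters, BIC-based selection of the
    calibration-error and noise models across a sensor cohort, and a
    synthetic-cohort generator emulating a 10-day clinical study design
    for parameter-recovery experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
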