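Package: scghr
Title: Multi-Point Seismocardiography Heart Rate Estimation with Fiber
    Bragg Grating Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating heart rate from multi-point
    seismocardiography (SCG) recorded by a four-element fiber Bragg
    grating (FBG) strain-sensor array embedded in a soft wearable patch.
    Implements the linear strain-to-wavelength-shift transduction model
    with calibration fitting and hysteresis-error metrics, a synthetic
    generator of supine-apnea recordings (aortic-opening-locked vibration
    bursts, reference ECG, synchronization trigger) with known ground
    truth, a documented multichannel CSV format with trigger-edge
    synchronization, the SCG processing chain (zero-phase Butterworth
    band filtering, FIR-Hilbert amplitude envelope, Welch dominant
    frequency, adaptive minimum-distance peak detection), and windowed
    heart-rate estimation with mean-absolute-error evaluation across
    sensor positions and single- versus multi-sensor (channel-sum)
    configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
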