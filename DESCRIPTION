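Package: cimscal
Title: Multipass Collision Cross Section Calibration for Cyclic Ion
    Mobility-Mass Spectrometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Calibrates collision cross section (CCS) measurements from
    multipass cyclic ion mobility-mass spectrometry (cIMS-MS) arrival-time
    data. Extracts precise arrival times from arrival time distributions by
    Gaussian nonlinear least squares, counts passes around the cyclic cell
    automatically from single-pass and bypass measurements, fits the linear
    model of total drift time on pass number to obtain perturbation-corrected
    periodic drift times, reconstructs wrap-around-split arrival time
    distributions, and builds power-law calibration curves with reduced-mass
    and charge scaling to predict CCS values for unknowns. Includes a
    synthetic arrival-time-data generator for end-to-end validation and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    readxl,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
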