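Package: vitalink
Title: Secure Vital-Sign Telemetry: PPG Simulation, Pulse-Oximetry
    Extraction, Encrypted Records, and Device-Agreement Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale computational core of an IoT vital-sign monitor.
    Synthesizes dual-wavelength (red/infrared) photoplethysmography
    waveforms and quantized temperature readings with known ground truth;
    estimates heart rate from inter-peak intervals and blood oxygen
    saturation via ratio-of-ratios calibration lines; encodes vital
    records with AES-128-CBC and Base64 through an in-process ciphertext
    store; and validates paired measured/reference reading tables with
    RMSE, MAE, mean relative error, linear correlation, and Bland-Altman
    limits of agreement. Ships three packaged device-validation tables
    and reproduces their summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
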