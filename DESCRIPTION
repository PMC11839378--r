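Package: beamprobe
Title: Overfitting Detection for Learned Ultrasound Beamformers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Probes deep-learning-based ultrasound beamformers for signs of
    overfitting without access to training code or data. Feeds artificial
    radiofrequency channel-data inputs (zeros, ones, Gaussian noise) to a
    beamformer-under-test, compares the outputs against a reference
    delay-and-sum plane-wave reconstruction with a quantitative metric suite
    (envelope mean and standard deviation, l1 and l2 losses, normalized cross
    correlation, structural similarity), runs a progressive channel-removal
    sweep, and emits a pass/overfit-suspected verdict. Includes a synthetic
    single-plane-wave linear-array channel-data simulator (point scatterers,
    diffuse speckle, electronic noise) so the whole protocol runs without
    external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
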