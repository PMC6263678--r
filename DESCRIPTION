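Package: barkline
Title: Resource-Efficient Classification of Dog Vocalization Events from
    Noise-Sensor Intensity Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a wearable noise sensor that reduces audio to
    peak-to-peak intensity levels (10-bit ADC, 0-5 V, 138 frames/s),
    preprocesses the resulting univariate time series (0-1 normalization,
    cubic-convolution interpolation), and classifies four dog sound-event
    classes (barking, growling, howling, whining) with an LSTM-FCN
    implemented on BLAS-backed matrix operations. Includes a
    class-conditional synthetic event generator, an RMSE similarity
    analysis between sound-derived and sensor-derived intensity, and the
    sensing/transmission/battery energy model that quantifies the noise
    sensor's resource advantage over a sound sensor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
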