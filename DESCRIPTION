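Package: accelequiv
Title: Inter-Device Equivalency of Raw Wrist Accelerometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study whether raw triaxial acceleration from one
    wearable activity monitor can stand in for another. Simulates
    orbital-shaker calibration trials and wrist-worn activity bouts through
    parametric accelerometer device models (gain, offset, noise, low-pass
    filter, quantization, clipping), verifies recorded output against the
    centripetal-acceleration closed form a = omega^2 * r, extracts
    time-domain and frequency-domain features of the triaxial vector
    magnitude over fixed windows, and quantifies how random-forest
    activity-type recognition accuracy degrades when a model trained on one
    device's data is applied to another's.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    randomForest,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
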