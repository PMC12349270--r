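Package: sbsdetect
Title: Wearable-Sensor Detection of Aggressive Infant-Shaking Movements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An analysis pipeline for detecting aggressive shaking movements
    indicative of Shaken Baby Syndrome from body-worn inertial measurement
    units. Simulates labeled infant-handling sessions (a protocol of 18
    handling tasks across 6 sensor positions at 100 Hz), segments the
    triaxial acceleration norm into 3 s windows with 1 s overlap, computes
    11 per-window descriptive statistics, fits a depth-2 Gini-impurity
    decision tree per sensor position, and reports confusion matrices with
    accuracy, precision, specificity, and sensitivity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
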