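Package: chewsense
Title: Food-Intake and Physical-Activity Recognition from Eyeglasses-Mounted Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for recognizing food intake and
    physical activity from a two-channel eyeglasses-mounted sensor system: a
    piezoelectric strain sensor over the temporalis muscle (chewing) and a
    three-axis accelerometer (gait). Provides a seeded multi-subject signal
    simulator, low-pass conditioning and 3-s epoch segmentation, four
    time-domain features per channel (range, standard deviation, energy,
    waveform length), two linear-SVM classification architectures (a single
    one-vs-all multiclass model on the fused feature vector, and a two-stage
    design fusing a chewing detector and a walking detector through decision
    rules), and leave-one-subject-out evaluation with confusion matrices,
    precision/recall/F1 and pooled one-vs-rest ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
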