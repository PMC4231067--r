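Package: pcgclassify
Title: Heart Sound Classification with LPC Features and a Cuckoo-Search-Tuned SVM Ensemble
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for automatic classification of phonocardiogram (PCG) heart
    sounds. Provides a seeded synthetic generator for twelve heart-sound
    classes (normal tones S1-S4, split tones, clicks, snaps and murmurs),
    variable-window heart-tone segmentation based on a normalized Shannon
    energy envelope, 24th-order Linear Predictive Coding (LPC) feature
    extraction via the Levinson-Durbin recursion, a one-against-others
    support vector machine ensemble with per-class kernels, and a Modified
    Cuckoo Search optimizer that jointly selects LPC features, kernel
    functions, kernel parameters and penalty terms under a leave-one-out
    balanced-accuracy fitness. Includes evaluation utilities (sensitivity,
    specificity, balanced accuracy, per-class report tables) and an
    end-to-end experiment driver with fixed-kernel SVM baselines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    e1071,
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
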