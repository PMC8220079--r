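Package: emgmotion
Title: Hand and Wrist Movement Decoding from Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Windowed time-domain feature extraction and feed-forward
    neural-network classification of hand and wrist movements from
    multichannel surface electromyography (sEMG), following the Ninapro
    acquisition protocol. Provides a MAT-file reader for Ninapro-style
    recordings, a synthetic sEMG generator with known class structure,
    sliding-window segmentation with repetition-wise train/test splitting,
    Hudgins time-domain features with noise thresholds for zero crossings
    and slope sign changes, a deep neural network classifier trained with
    Adam, imbalance-aware evaluation (overall accuracy and macro-averaged
    recall, precision and F1), noise-threshold grid search, and
    full-sequence usage simulation with prediction-continuity statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
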