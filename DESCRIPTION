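Package: stethkit
Title: Heart-Sound Screening from Phonocardiogram Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An at-home heart-sound screening toolkit for phonocardiogram
    (PCG) audio. Synthesizes labelled heart-sound clips (normal beats and
    ejection-systolic, pansystolic and diastolic murmurs), normalizes
    recordings to a fixed rate and duration, compresses them with
    per-frame linear predictive coding (Levinson-Durbin), extracts the
    standard spectral/cepstral feature set (MFCCs, chroma, centroid,
    bandwidth, rolloff, RMSE, zero-crossing rate), augments classes with
    Gaussian-mixture sampling, trains a family of small convolutional and
    recurrent networks, routes clips through a hierarchical
    normal/murmur -> systolic/diastolic -> ESM/PSM cascade, attributes
    decisions to named features with Shapley-value estimation, and
    evaluates with confusion matrices, confidence intervals and an exact
    binomial test against a chance baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
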