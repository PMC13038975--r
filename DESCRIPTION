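Package: microlabel
Title: Polarity-Considered EEG Microstate Labeling and Oddball Stimulus Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms epoched multichannel EEG into one-dimensional
    microstate label sequences using polarity-signed template maps and a
    winner-take-all spatial correlation rule, then classifies rare ("target")
    versus frequent ("standard") oddball stimuli from those sequences.
    Includes task-specific template derivation (global field power peak
    extraction and polarity-invariant modified K-means clustering with
    eigenvector centroid updates), label occurrence-frequency maps, temporal
    generalization matrices, nested cross-validated classification with
    several model families, cluster-based permutation statistics on
    time-resolved label distributions with false discovery rate correction
    across labels, template-weighted topographic reconstruction scored by
    global map dissimilarity, and a synthetic oddball session generator with
    planted microstate dynamics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
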