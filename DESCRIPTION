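Package: songspace
Title: Perceptual Similarity Spaces for Birdsong Syllables from Operant AXB Judgments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for learning and validating measures of birdsong syllable
    similarity against two-alternative (AXB) perceptual judgments made by
    birds in operant experiments. Includes a synthetic generator for zebra
    finch like syllables and simulated operant decision logs; acoustic
    feature extraction (log-power mel spectrograms and per-frame feature
    contours); weighted dynamic time warping dissimilarities with
    Metropolis-Hastings calibration of feature weights against behavioural
    triplets; a convolutional triplet-embedding network with an
    ambiguity-aware loss; an evaluation harness (AXB accuracy with bootstrap
    intervals, attainable-accuracy bounds, disagreement MDS, choice
    calibration curves, ingestion of external dissimilarity matrices); and
    multiple regression on distance matrices (MRM) with permutation
    inference for acoustic feature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
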