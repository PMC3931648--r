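Package: accelknn
Title: Behavioural Classification of Tri-Axial Accelerometer Data by
    K-Nearest Neighbours
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies raw tri-axial acceleration time series into animal
    behavioural modes with a k-nearest neighbour classifier operating
    directly on the (x, y, z) acceleration triples, in g, with no summary
    statistics or windowing.  Provides the classifier's majority-vote
    confidence output (the proportion of the k neighbours in the winning
    class), a minimum-majority threshold filter that discards low-confidence
    classifications, discard-aware confusion-matrix accounting with
    accuracy, precision and recall, threshold sweeps with Spearman rank
    correlations of each metric against the threshold, and a synthetic
    accelerometer-signal generator (static gravity posture plus sinusoidal
    dynamic components plus Gaussian noise) for building labelled training
    and testing sets.  Includes a command-line interface tying simulation,
    classification and evaluation together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
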