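Package: ackmeans
Title: Adaptively Constrained K-Means Clustering for Cryo-EM 2D
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Unsupervised 2D classification of single-particle cryo-EM
    images with an adaptively constrained K-means algorithm (ACK-means)
    that penalizes unbalanced class sizes through a scale-free constraint
    term, alongside traditional K-means, a SPIDER-style size-factor
    variant, and equally-sized-group K-means (EQK-means) baselines.
    Includes a ground-truth benchmark simulator (projections of an
    asymmetric phantom density from Gaussian-clustered hemisphere
    orientations, contrast-transfer-function modulation, additive
    Gaussian noise at a target signal-to-noise ratio, phase flipping),
    a simplified multi-reference-alignment dissimilarity, evaluation
    instruments (within-class angular-distance histograms, class-size
    balance curves, membership-change convergence traces, adjusted Rand
    index), MRC/MRCS stack I/O, and a reproducible simulate-cluster-
    evaluate pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
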