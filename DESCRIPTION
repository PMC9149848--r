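Package: sartdysreg
Title: Longitudinal SART Bad-Performance Analysis with Fuzzy Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal Sustained Attention to
    Response Task (SART) data in ageing cohorts. Derives the thresholded
    'bad performance' statistic from raw go/no-go trial logs, partitions
    participants by fuzzy c-means clustering on the two-wave bad-performance
    trajectory with an elbow scan over the within-cluster sum of squares,
    characterises the resulting clusters for mobility and cognitive decline
    (Timed Up-and-Go, gait speeds, falls, MMSE, MoCA), and fits nested binary
    logistic regression models predicting future bad performances. Includes a
    seeded synthetic cohort generator with three latent trajectory classes so
    that the full pipeline is testable without access-restricted cohort data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
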