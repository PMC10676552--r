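Package: ppbnet
Title: QSAR Pipeline for Human Plasma Protein Binding with Neural Network
    Regression and Applicability Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR) models
    of the plasma protein-bound fraction of drugs from wide molecular
    descriptor tables. Provides a five-stage descriptor filter cascade
    (constant, quasi-constant, relative standard deviation, pairwise
    correlation, variance inflation factor), a single-hidden-layer tanh
    feed-forward network trained by Levenberg-Marquardt least squares with a
    hidden-neuron growth search, internal and external validation statistics
    (R, R squared, adjusted R squared, Q squared from PRESS, MSE, RMSE, MAE),
    four applicability-domain assessments (PCA bounding box, centroid
    distance percentile, k-nearest-neighbour distance at k = 5 and k = 25)
    with a leverage diagnostic, and a seeded synthetic-data generator that
    emulates the statistical pathologies of large descriptor matrices so the
    whole pipeline is testable without proprietary descriptor software.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
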