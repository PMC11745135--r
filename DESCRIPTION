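Package: scorpsize
Title: Phylogenetic Allometry and Body-Size Prediction for Scorpions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for predicting scorpion body size (total length and
    carapace length) from single linear measurements of body parts using
    allometric log-log equations fitted under a phylogenetic framework.
    Provides ready-to-use predictive equations for buthid scorpions with
    published coefficient sets, and the full pipeline that derives such
    coefficients: phylogenetically informed random-forest imputation of
    missing trait values with masked-reimputation validation, phylogenetic
    principal component analysis under Pagel's lambda, Bayesian phylogenetic
    mixed linear models fitted by Gibbs sampling with species-level repeated
    measures, RMSE-based predictor ranking, and a synthetic-data generator
    producing ultrametric trees and allometrically structured traits with
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    randomForest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phytools,
    withr
Config/testthat/edition: 3
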