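Package: stackppi
Title: Stacked Attention Ensembles for Protein-Protein Interaction Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts protein-protein interactions from sequence alone.
    Proteins are encoded with four classical sequence descriptors (auto
    covariance over seven physicochemical properties, conjoint triads over a
    seven-group alphabet, local composition/transition/distribution
    descriptors over ten sequence regions, and pseudo amino acid
    composition), pairs are modelled by a convolutional network with
    multi-head scaled dot-product cross-attention and a merge layer, and
    sixteen such basic learners are combined by stacked generalization with
    five-fold out-of-fold meta-features and a neural meta-learner. Includes
    dataset construction (length and identity filters for positives,
    subcellular-localization-based negative sampling at a 1:1 ratio), a
    synthetic proteome/interactome generator with a planted
    motif-complementarity signal for offline testing, evaluation metrics,
    and an end-to-end pipeline with caching and run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tools,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    glmnet,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
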