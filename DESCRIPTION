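Package: bridgesyn
Title: Bridge-Token Fusion Models for Drug Combination Synergy Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trainable implementation of the BridgeSyn framework for
    predicting drug combination synergy scores in cancer cell lines.
    Drug token embeddings and expression-enriched gene matrices are
    projected into a shared space, compressed with a k-nearest-neighbour
    density-peaks clustering (DPC-KNN) cell-line encoder, fused through
    iterative bridge-token cross-attention layers, and refined by a
    dual-path residual prediction head. Includes the leave-cell-out and
    leave-combination-out evaluation protocols, perturbation and
    integrated-gradients drug attribution, order-sensitivity analysis,
    and a synthetic data generator with a known ground-truth synergy
    function for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
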