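Package: glottolearn
Title: Compression-Based Learning Difficulty of Languages and Its Association
    with Speaker Population Size
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates how difficult languages are for sequence models to learn
    from text, using two compression-based measures: the shape parameter of a
    learning-curve ansatz fitted to incremental compression rates, and
    per-language random slopes (BLUPs) from a mixed model of fold-rotation
    cross entropies. Provides a prediction-by-partial-matching code-length
    oracle with exact bit accounting, byte-pair encoding, verse-parallel corpus
    handling, and a synthetic-world generator with known ground truth. Tests the
    association between learning difficulty and speaker population size while
    controlling for phylogenetic relatedness and geographic proximity via
    multi-model mixed-effects inference with frequentist model averaging,
    double-selection lasso with Freedman-Lane permutation tests, phylogenetic
    generalized least squares, and spatial autoregressive error models with two
    weighting matrices and permutation inference.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    ape,
    lme4,
    glmnet,
    minpack.lm,
    sandwich,
    stats,
    utils,
    splines,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme,
    geosphere
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
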