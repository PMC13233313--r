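Package: actionsym
Title: Behavioural and Neural Analysis of Stroke Primitives as Action Symbols
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for analysing drawing-like motor behaviour and
    simultaneously recorded frontal-cortex population activity in terms of
    stroke primitives (action symbols). Implements a regularized dynamic time
    warping trajectory distance over normalized velocity series, a modified
    Hausdorff image distance, primitive alignment scoring and categorical morph
    analysis, template-based stroke classification with a remixed-primitive
    null, an adaptive behavioural scoring engine, spike-rate preprocessing
    (Gaussian smoothing, unit screening, soft z-scoring, linear trial time
    warping), and population-geometry analyses (condition-averaged PCA,
    debiased neural distance, encoding strength, cross-condition decoder
    generalization, initial-reach correction, and linear kinematic encoding
    models scored by the fraction of variance accounted for). A synthetic-data
    module generates strokes, morph sets, characters, and tuned population
    tensors so every stage runs without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
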