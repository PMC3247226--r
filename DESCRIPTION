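Package: regnann
Title: Gene Regulatory Network Inference with Ensembles of Per-Gene Neural Regressors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reverse engineering of undirected gene regulatory networks from
    steady-state expression data using an ensemble of one-to-many multilayer
    perceptron regressors, one per gene, trained by online back-propagation
    with momentum and probed at maximal input to yield a correlation matrix
    that is thresholded (or majority-voted) into a network. Includes synthetic
    benchmark generators (Barabasi-Albert and Erdos-Renyi topologies, linear
    correlation expression synthesis, four toy regulatory motifs), the
    normalization schemes studied alongside the method (linear rescaling,
    statistical normalization, sign discretization), evaluation by recall,
    precision and the Matthews correlation coefficient including
    precision-recall and MCC-recall curves with trapezoidal AUC, threshold
    grid search with train/validation splits, and a desk-scale experiment
    harness for repeated generate-infer-score protocols with mean and twice
    standard deviation reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    purrr,
    ggplot2,
    readr,
    rlang,
    jsonlite,
    generics,
    yaml,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
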