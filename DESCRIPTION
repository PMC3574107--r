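Package: toxorder
Title: Order-Classification of Chemical Toxicity from Weighted
    Chemical-Chemical Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts ranked ("order") multi-label toxicity profiles for
    chemical compounds by guilt-by-association over a weighted
    chemical-chemical interaction network in the STITCH combined-score
    dialect. Each of seven toxicity categories (acute toxicity,
    mutagenicity, tumorigenicity, skin and eye irritation, reproductive
    effects, multiple dose effects, and non-toxicity) is scored for a
    query compound as the confidence-score-weighted vote of its
    interactive training compounds, and categories are reported in
    descending score order with zero-score categories excluded. Includes
    the evaluation protocol for such order classifiers (leave-one-out
    jackknife, per-order accuracies, first-m coverage, mean-label-count
    baseline, stratified multi-label train/test splits), pairwise
    category co-occurrence analysis, and a reproducible generator of
    homophilous labeled benchmark networks for testing without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
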