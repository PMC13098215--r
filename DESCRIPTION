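Package: nfbiome
Title: Microbiome and Metabolite Classification of Neutropenic Fever
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end workflow for distinguishing infectious from
    non-infectious neutropenic fever using gut microbiome relative
    abundances, targeted fecal metabolites, and clinical covariates.
    Provides a synthetic cohort simulator with planted ground truth,
    compositional preprocessing (prevalence/abundance filtering, centered
    log-ratio transform with a dataset-wide pseudocount, collinearity
    pruning), ecological diversity statistics (Shannon index,
    Kruskal-Wallis with Dunn post hoc, Bray-Curtis and UniFrac distances,
    PERMANOVA with pairwise post hoc tests), univariate feature screening,
    an aggregate gradient-boosted-tree classification framework with
    repeated stratified splits, importance-threshold biomarker selection
    and SHAP interpretation, and biomarker-centered Spearman correlation
    networks with two-level adjacency extraction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    permute,
    ape,
    phyloseq,
    igraph,
    xgboost,
    pROC,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    picante,
    optparse
Config/testthat/edition: 3
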