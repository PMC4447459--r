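Package: gmwrf
Title: Two-Stage miRNA Biomarker Screening with Directional Rank Tests
    and Random Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a two-stage screening pipeline for ordered
    three-group expression studies (healthy, non-aggressive and
    aggressive disease): a generalized Mann-Whitney directional test
    based on probabilistic indices over ordered triples with permutation
    p-values, combined with repeated random-forest Gini-importance
    ranking to select high-interest (HI) probes.  Includes probe
    detection filtering and quantile normalization, Kendall-tau distance
    clustering with adjusted Rand index evaluation, cis-eQTL mapping
    with genotype-group rank tests, Fisher exact case-control
    association on 2x3 genotype tables with replication, comparator
    selectors (one-way ANOVA with Bonferroni correction and two-stage
    lasso logistic regression), and a synthetic cohort generator with
    planted ground truth for calibration and parameter-recovery testing.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    randomForest,
    glmnet,
    limma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
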