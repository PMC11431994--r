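Package: antmorph
Title: Morphospace Null Models for Polymorphic Ant Worker Traits
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing intraspecific morphological variation of
    polymorphic ant workers across environmental gradients. Standardizes
    worker trait tables and extracts varimax-rotated principal components,
    then tests two hypotheses about how environments structure morphospace:
    environmental filtering (convex-hull volume of a population below a
    pooled-null expectation) and optimal transfer (centroid displacement of
    a population above the null), using stratified colony-aware subsampling
    and Mann-Whitney U comparisons. Also provides the Scheirer-Ray-Hare
    two-way rank test with Bonferroni correction, Huber M-estimation robust
    regression of component scores on environmental covariates, and a
    synthetic-data generator with planted variance-shrink, centroid-shift
    and environment-slope effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
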