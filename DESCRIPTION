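Package: mdseq
Title: Multiple Degree of Freedom Testing for Repeated-Measures RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation toolkit for joint (multiple degree of
    freedom) hypothesis testing in longitudinal and other correlated bulk
    RNA-seq designs. Generates negative binomial counts with gene-specific
    dispersion and subject random intercepts for a two-group, multi-timepoint
    design; fits per-gene models by four correlated-data approaches (linear
    mixed models on variance-stabilized counts, negative binomial mixed models
    by adaptive Gauss-Hermite quadrature or pseudo-likelihood, and generalized
    estimating equations with a small-sample sandwich covariance); evaluates
    between-subject, within-subject, interaction and global contrasts by Wald
    chi-square, Satterthwaite F or likelihood-ratio tests; and summarises false
    discovery rate, power and model convergence across replicate datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    glmmTMB,
    jsonlite,
    lme4,
    lmerTest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
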