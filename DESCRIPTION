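Package: pinegp
Title: Multi-Trait Genomic Prediction and GWAS for Open-Pollinated Conifer Progeny Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative genomic analysis of multi-site, multi-trait
    open-pollinated progeny trials genotyped with SNP dosages. Implements SNP
    filtering and mean-frequency imputation, VanRaden genomic relationship
    matrices, single- and multi-trait GBLUP mixed models fitted by EM-REML with
    a terminal average-information step for approximate standard errors,
    genome-wide association by back-solving SNP effects from genomic breeding
    values, single-trait Bayesian whole-genome regressions (Bayesian ridge,
    BayesC, Bayesian lasso), Gaussian-kernel RKHS regression, multi-trait Gibbs
    samplers with trait-assisted prediction, cross-validation with predictive
    ability, accuracy and bias statistics, and ANOVA/Tukey method comparison.
    A seeded simulator of open-pollinated families, Mendelian SNP genotypes and
    correlated multi-site phenotypes provides ground-truth test beds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite,
    yaml,
    multcomp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
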