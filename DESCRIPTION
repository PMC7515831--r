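Package: temperanet
Title: Data-Driven Genotype-Phenotype Network Analysis for Temperament
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A data-driven pipeline for uncovering many-to-many
    genotype-phenotype relations in temperament genome-wide association
    studies. Discovers possibly overlapping SNP sets (genotype biclusters)
    and temperament sets by non-negative matrix factorization with
    cophenetic-correlation rank selection, tests SNP sets against an
    empirical temperament index with a kernel (SKAT-style) variance
    component score test, maps set-by-set relations with hypergeometric
    enrichment and permutation nulls, fuses relations with well-being and
    ill-being indices, estimates SNP heritability by trimmed
    cross-validated ridge regression, matches discovered sets across
    cohorts under Pareto multi-objective ranking, and classifies phenotype
    membership from genotype-set membership. Includes a seeded synthetic
    cohort generator with planted biclusters, population structure, and
    ground truth for scoring every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    pROC,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
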