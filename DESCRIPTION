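Package: ccoda
Title: Covariate-Corrected Dispersion Analysis for Metagenomic Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies gene families in shotgun-metagenome count data whose
    abundance across samples is significantly more or less variable than
    expected given their mean, while integrating samples from multiple
    studies. Counts are normalized to log reads-per-kilobase-of-genome-
    equivalents (RPKG), study effects are removed with a linear model, and
    the residual variance of each gene family is compared against a
    negative-binomial parametric-bootstrap null with per-study dispersion
    estimated by the mode of per-gene method-of-moments estimates. Includes
    a simulation framework for power and type-I-error evaluation and
    empirical false-discovery-rate calibration, partial Kendall's tau
    permutation tests for associations with clinical and taxonomic
    covariates, Fisher-exact gene-set enrichment, zero-inflation screening,
    and phylogenetic-distribution (tree density) scoring of gene-family
    trees.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    glmmTMB,
    phangorn,
    purrr,
    rlang,
    readr,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
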