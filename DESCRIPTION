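Package: famrisk
Title: Two-Stage Familial Cancer Risk Gene Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a two-stage strategy for discovering cancer risk
    genes from cancer-cluster families. Stage one prioritizes germline
    variants found in multigenerational pedigrees ascertained through an
    affected proband: caller intersection, annotation-driven
    categorization (rare private, known rare, candidate gene),
    measured-genotype association under a polygenic variance-component
    model (Gaussian for quantitative outcomes, liability-threshold for
    binary outcomes) with a probit ascertainment-weight covariate, and a
    strict complete-penetrance segregation filter. Stage two validates
    prioritized genes in an independent case/control cohort by gene-level
    rare-variant burden tests: allele-count contingency tables for
    deleterious and regulatory variant classes, one-sided Fisher exact
    tests, odds ratios, and Bonferroni correction. A synthetic-data module
    generates pedigrees, genotypes, liability-model phenotypes and
    case/control cohorts with the statistical structure the analysis
    assumes, so the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    mvtnorm,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
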