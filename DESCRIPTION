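Package: pathrank
Title: Competitive Pathway Enrichment Tests on Scaled Ranks of GWAS Gene
    P-Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Adapts classical p-value combination tests to the competitive
    (enrichment) null hypothesis of pathway analysis by replacing gene
    p-values with their scaled ranks across the whole study. Implements
    Fisher's method, the Tail Strength Measure, the adaptive rank truncated
    product with Ge's single-level permutation algorithm, a weighted
    Kolmogorov-Smirnov enrichment score, and the hypergeometric
    over-representation test, together with gene-label permutation and
    empirical-uniform null calibration. Ships a quantitative-trait GWAS
    simulator (Hardy-Weinberg genotypes, sparse random SNP effects,
    additive phenotype, single-SNP regression) and a scenario driver for
    estimating type-I error and power, plus SNP-to-gene mapping and
    permutation-based gene p-value adjustment for real study inputs.
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
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
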