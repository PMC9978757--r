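Package: cytomr
Title: Bi-Directional Mendelian Randomisation and Colocalisation for
    Circulating Cytokines and Cardiometabolic Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-sample Mendelian randomisation (MR) and
    approximate-Bayes-factor colocalisation between circulating cytokine
    levels and cardiometabolic traits. Covers GWAS summary-statistic
    input/output and allele harmonisation, inverse-variance-weighted
    fixed-effects meta-analysis across cohorts and tissues, cis-pQTL /
    cis-eQTL / genome-wide instrument selection with greedy LD clumping,
    the Wald ratio, IVW, weighted-median, MR-Egger and MR-PRESSO
    estimators, enumeration-based colocalisation with shared/distinct
    posterior decision rules, and orchestration of the three analysis
    directions (risk factors to cytokines, cytokine to cytokine with a
    causal network, cytokines to outcomes). A synthetic-cohort generator
    with block linkage disequilibrium and configurable causal structure
    supports end-to-end validation against known ground truth.
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
    igraph,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
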