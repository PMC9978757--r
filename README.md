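# cytomr

Bi-directional Mendelian randomisation (MR) and colocalisation between
circulating cytokines and cardiometabolic traits.

Inflammatory cytokines are candidate drug targets for cardiovascular
disease, but observational associations between risk factors, cytokine
concentrations and outcomes are confounded in both directions. `cytomr`
implements the genetic-epidemiology pipeline that addresses this with
summary-level GWAS data: genetic variants serve as randomly allocated
instruments for each exposure, and Bayesian colocalisation distinguishes a
shared causal variant from confounding by a nearby distinct one. It is
written for statistical geneticists and epidemiologists who want the whole
chain — from per-cohort GWAS to the cytokine causal network — as tested,
seedable, tibble-native R functions.

## What it computes

* **Summary statistics**: TSV input/output, allele harmonisation across
  sources (swaps, strand flips, palindrome rules), LD matrices, BED gene
  loci (`read_sumstats()`, `harmonise()`, `ld_from_dosages()`).
* **Meta-analysis**: inverse-variance-weighted fixed effects across
  cohorts, and across eQTL tissues (`meta_fixed()`,
  `aggregate_tissues()`).
* **Instrument selection**: greedy LD clumping (`r² < 0.001`) under four
  criteria — genome-wide trait instruments (`p < 5×10⁻⁸`; `1×10⁻⁶` for
  fasting insulin), *cis*-pQTL (gene ± 500 kb, cytokine `p < 1×10⁻⁴`),
  *cis*-eQTL (gene ± 500 kb, cross-tissue expression `p < 1×10⁻⁴` and
  cytokine `p < 0.05`), and genome-wide cytokine instruments.
* **MR estimators**: Wald ratio `β_out/β_exp`; IVW (weighted regression
  through the origin, multiplicative random-effects SE inflation
  `√max(1, Q/(n−1))`); weighted median (bootstrap SE); MR-Egger (free
  intercept = directional pleiotropy); MR-PRESSO (simulation-based global,
  outlier and distortion tests). `run_mr()` dispatches by instrument
  count; odds ratios per 1 SD via `or_from_beta()`.
* **Colocalisation**: Wakefield approximate Bayes factors
  `0.5(log(1−r) + r z²)`, `r = w/(w+se²)`, enumerated into posteriors
  PP(H0)…PP(H4); decision rules `PP_shared+PP_distinct > 0.5` and
  `PP_shared/(PP_shared+PP_distinct) > 0.5` (`colocalise()`).
* **Pipeline**: the three analysis directions (risk factors → cytokines,
  cytokine → cytokine with a community-partitioned causal network,
  cytokines → outcomes), Bonferroni family thresholds
  (`0.05/47 = 0.0011`, `0.05/15 = 0.0033`), criterion comparison by
  Pearson correlation, z-score matrices and ggplot2 figures.
* **Synthetic cohorts**: block-LD genotypes, trait DAGs, pleiotropy,
  per-tissue expression and per-variant GWAS with known ground truth
  (`sim_config()`, `simulate_cohort()`, `run_gwas()`), used by the test
  suite and validation studies.

## Worked example

Simulate a cohort in which cytokine `VEGF_like` has one cis causal
variant and raises `IL18_like` by 0.5 SD, then run the cytokine→cytokine
direction end to end:

```r
library(cytomr)
library(tibble)

loci <- rbind(gene_locus("VEGF_like", "1",  499000,  501000),
              gene_locus("IL18_like", "1", 1499000, 1501000))
cfg <- sim_config(
  n_individuals = 5000, n_variants = 40, ld_block_size = 10, ld_rho = 0.6,
  maf_range = c(0.1, 0.5), pos_spacing = 50000L,
  traits = tibble(trait_id = c("VEGF_like", "IL18_like"),
                  type = "cytokine", noise_sd = 1, prevalence = NA_real_),
  causal_map = tibble(trait_id = "VEGF_like", variant = 10L, beta = 0.5),
  trait_dag  = tibble(from = "VEGF_like", to = "IL18_like", beta = 0.5),
  gene_loci = loci, seed = 2026)
cohort    <- simulate_cohort(cfg)
cytokines <- lapply(c("VEGF_like", "IL18_like"), \(t) run_gwas(cohort, t))
ld        <- ld_from_dosages(cohort$dosages)

d2 <- run_direction_2(cytokines, ld, loci,
                      config = pipeline_config(mr = mr_config(seed = 2026)))
d2$rows[, c("exposure", "outcome", "criterion", "method", "n_snp",
            "beta", "se", "p", "significant", "coloc_supported")]
#> # A tibble: 1 × 10
#>   exposure  outcome   criterion method n_snp  beta     se        p significant
#>   <chr>     <chr>     <chr>     <chr>  <int> <dbl>  <dbl>    <dbl> <lgl>
#> 1 VEGF_like IL18_like cis_pqtl  ratio      1 0.512 0.0430 1.19e-32 TRUE
#>   coloc_supported
#>   <lgl>
#> 1 TRUE
```

One cis-pQTL instrument was selected at the `VEGF_like` locus, so the
Wald ratio is the main analysis: a 1 SD rise in genetically proxied
`VEGF_like` raises `IL18_like` by 0.51 SD (the planted effect is 0.5),
far past the family threshold `0.05/2`. Colocalisation at the exposure
locus confirms the signals share one causal variant:

```r
d2$rows$coloc[[1]]
#> <colocalisation> 20 variants
#> PP_H0 PP_H1 PP_H2 PP_H3 PP_H4
#>     0     0     0     0     1
#> support rule (PP_shared + PP_distinct > 0.5): TRUE
#> ratio rule (PP_shared / (PP_shared + PP_distinct) > 0.5): TRUE
```

The reverse direction is skipped for lack of instruments
(`attr(d2$rows, "skipped")` reports `IL18_like (cis_pqtl): no
instruments`), and `d2$graph` holds the significant directed edges with
community labels. `tidy()`/`glance()` methods give broom-style tables for
every result type, and `plot_mr_scatter()`, `plot_z_matrix()`,
`plot_coloc()` the corresponding figures.

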