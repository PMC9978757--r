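---
title: "Methods: bi-directional MR and colocalisation for circulating cytokines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bi-directional MR and colocalisation for circulating cytokines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytomr)
```

## The scientific problem

Circulating cytokines sit between classical cardiometabolic risk factors
(adiposity, blood pressure, lipids, smoking) and cardiovascular outcomes.
Observational associations among these quantities are confounded in both
directions, so `cytomr` implements the genetic-epidemiology toolkit used to
probe them causally: two-sample Mendelian randomisation (MR), in which
genetic variants serve as randomly allocated instruments for a modifiable
exposure, combined with Bayesian colocalisation, which asks whether the
exposure and outcome association signals at a locus are driven by the same
causal variant or merely by two variants in proximity.

The package orchestrates three analysis directions over a set of cytokine
and cardiometabolic GWAS summary statistics:

1. risk factors → cytokine concentrations (genome-wide instruments);
2. cytokine → cytokine, with colocalisation at the exposure gene locus and
   a directed causal network;
3. cytokines → cardiometabolic outcomes, with colocalisation for nominally
   significant pairs and odds-ratio reporting for binary outcomes.

Because the consortium-scale summary statistics behind any real analysis
are external data, the package carries a synthetic-cohort generator with
fully known ground truth; every statistical property claimed for the
pipeline is demonstrated on that generator by the test suite and the
acceptance script, and nothing in this vignette states a number those runs
do not themselves compute.

## Summary statistics and harmonisation

Summary statistics are tibbles with one row per variant (id, chromosome,
position, effect and other allele, effect-allele frequency, beta, SE, p,
n), carrying trait identity as attributes. Betas are per effect-allele
copy, in SD units for quantitative traits and log-odds for binary traits.

Two-sample MR needs exposure and outcome effects expressed for the same
allele. `harmonise()` matches variants on (chromosome, position) rather
than on identifier strings, because identifier dialects (rsID vs
chr:pos) differ across sources; alleles are then reconciled allowing label
swaps (outcome beta changes sign, frequency reflects) and strand flips.
Palindromic variants (A/T, C/G) cannot be strand-resolved from labels;
they are kept only when both traits' effect-allele frequencies fall on the
same side of 0.5 and the minor-allele frequency is below
`palindrome_eaf_limit` (default 0.42, the usual cut-off for confident
strand inference — the choice is exposed because reasonable analyses
differ here). Indels and multi-allelic positions are dropped: the analyses
this package supports are SNP-based. Coordinates are 1-based inclusive
everywhere internally; BED input is converted on read.

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` produce individual-level data:

* **Genotypes.** Haplotypes come from a Gaussian copula: within blocks of
  `ld_block_size` adjacent variants the latent normals follow an AR(1)
  correlation `ld_rho^distance`; thresholding at the MAF quantile gives
  0/1 alleles, and two haplotypes sum to a dosage. This gives block LD
  with controllable decay at trivial cost; it deliberately does not model
  recombination hotspots, demography, relatedness or imputation noise, so
  passing tests show the pipeline's statistical behaviour under clean
  additive genetics, not robustness to real-data artefacts.
* **Phenotypes.** Each quantitative trait is a sum of configured per-allele
  variant effects, upstream-trait effects along an acyclic trait DAG, and
  Gaussian noise; binary traits threshold this liability at the empirical
  quantile matching the configured prevalence. Direct variant-on-outcome
  (pleiotropic) effects are expressed as extra causal-map rows for the
  outcome trait.
* **Expression.** Per (gene, tissue), configured cis variants act with a
  tissue-shared component plus a tissue-specific normal perturbation,
  emulating the cross-tissue eQTL structure the cis-eQTL criterion
  aggregates over.
* **Two-sample designs.** A separate `panel_seed` fixes MAFs and allele
  labels so that independent cohorts can be genotyped on an identical
  panel.

`run_gwas()` fits the additive model per variant: vectorised OLS for
quantitative traits (covariates handled by Frisch–Waugh residualisation),
per-variant logistic regression for binary traits, Wald two-sided
p-values. Cytokines are rank-based inverse-normal transformed by default
(Blom offset 3/8), matching standard practice for skewed cytokine
panels; the transform is a switch because cohort pipelines differ.
Monomorphic variants are emitted with `se = Inf` so that selection rather
than I/O removes them. Sparse binary cells are left to these sanity bounds
rather than a Firth fallback — at simulated prevalences (0.2–0.3) and desk
sample sizes separation essentially never occurs.

## Meta-analysis

`meta_fixed()` pools cohorts by inverse-variance-weighted fixed effects:
weights `1/se^2`, pooled SE `(sum w)^(-1/2)`. Variants carried by any
cohort are emitted, with `k_studies` recording contributors; no
heterogeneity filtering is applied at this stage. Cross-tissue eQTL
aggregation (`aggregate_tissues()`) reuses the same machinery — the
simplest choice consistent with "aggregated across tissues" — with a
Stouffer z combination available as an alternative because the aggregation
method is a genuinely open choice; the per-variant cross-tissue z and the
whole-blood-only z are both reported to support their comparison.

## Instrument selection

`clump()` implements greedy LD pruning: candidates below the p threshold
are ranked by p (ties by position then allele strings, making the output
deterministic and order-invariant), accepted greedily, and later
candidates with `r² ≥ r2_max` against an accepted variant are discarded.
Thresholds are strict (`p < x`), matching the `P<x` convention of the
selection rules; window bounds are positional and inclusive.

Four criteria produce instrument sets:

| criterion | window | thresholds | clumping |
|---|---|---|---|
| `trait_gwas` | genome-wide | `p < 5e-8` (fasting insulin `1e-6`) | `r² < 0.001` |
| `cis_pqtl` | gene ± 500 kb | cytokine `p < 1e-4` | `r² < 0.001` |
| `cis_eqtl` | gene ± 500 kb | expression `p < 1e-4` AND cytokine `p < 0.05` | `r² < 0.001` |
| `genomewide_cytokine` | genome-wide | cytokine `p < 5e-8` | `r² < 0.001` |

cis windows anchor to the gene body (not the TSS) since the selection is
phrased in terms of the gene locus. Cis instruments are clumped at the
same `r² < 0.001` as genome-wide ones: the ratio/IVW estimators assume
uncorrelated instruments, so near-independence is enforced uniformly; the
ceiling is a parameter for users who prefer a looser cis rule. cis-eQTL
exposure betas are taken from the cytokine (not expression) statistics so
estimates remain on the circulating-protein scale. Instrument strength
(F-statistics) is a reporting concern, not a filter, and Steiger-type
direction filtering is out of scope.

## The MR estimator suite

For a harmonised set with effects `bx ± sex`, `by ± sey`:

* **Wald ratio** (1 instrument): `by/bx`, first-order delta SE
  `sey/|bx|`. The second-order term and the exposure-error contribution
  are omitted — the standard leading-order default.
* **IVW** (≥ 2): weighted regression of `by` on `bx` through the origin,
  weights `1/sey²`. The fixed-effects SE is inflated by
  `sqrt(max(1, Q/(n−1)))` (multiplicative random effects, floored at 1),
  so the estimator reduces to plain fixed effects when heterogeneity is at
  or below expectation. This is the dominant practice when the
  fixed-vs-random choice is not otherwise specified.
* **Weighted median** (≥ 3): per-variant ratios weighted by `bx²/sey²`;
  the estimate interpolates the weighted ratio CDF at 0.5 (an exact hit
  returns that ratio). Its SE is the SD over `n_boot = 1000` seeded
  parametric-bootstrap replicates. Consistent while valid instruments
  carry ≥ 50% of weight.
* **MR-Egger** (≥ 3): weighted regression with a free intercept after
  orienting all `bx > 0`; the intercept estimates average directional
  pleiotropy, and SEs carry the same floored dispersion factor (here with
  `n−2` degrees of freedom).
* **MR-PRESSO** (≥ 4): observed residual sum of squares around
  leave-one-out IVW estimates, compared against `n_sim = 1000` parametric
  simulations; add-one empirical p-values avoid exact zeros. Per-variant
  residuals against their own simulated distributions give outlier flags
  at `0.05/n_snp`; when outliers are found the headline estimate switches
  to the outlier-removed IVW (standard PRESSO reporting) and a distortion
  p compares the observed estimate shift with that from removing random
  subsets of the same size.

`run_mr()` dispatches on instrument count — ratio at 1, IVW at 2+, adding
weighted median and Egger at 3+ and PRESSO at 4+ — labelling the first
result "main" and the rest "sensitivity"; the main estimate alone drives
significance flags downstream. Generalised (correlated-instrument) IVW is
not implemented: instruments arrive pre-clumped to near-independence. All
estimators are invariant to joint allele flips and equivariant under
outcome rescaling; both properties are asserted in the tests.

## Colocalisation

Per variant, Wakefield's log approximate Bayes factor
`0.5·(log(1−r) + r·z²)` with shrinkage `r = w/(w + se²)` measures evidence
against the point null under a normal effect prior with variance `w`
(0.2² for quantitative traits, 0.15² on the log-odds scale for binary
outcomes). `colocalise()` combines these with per-variant priors
`p1 = p2 = 1e-4`, `p12 = 1e-5` — the method's canonical defaults, exposed
in `coloc_config()` since no analysis-specific priors are mandated — into
posteriors over the five hypotheses H0–H4. All accumulation is in log
space with log-sum-exp; the H3 term (all ordered pairs of distinct causal
variants) is the stably computed difference
`logsumexp(l1)+logsumexp(l2) − logsumexp(l1+l2)`, guarded to −∞ when the
difference underflows, so loci with z-scores in the tens do not overflow.
A single-variant locus makes H3 combinatorially impossible (PP exactly 0)
and is flagged degenerate.

The decision rule follows the two-part convention: *support*
(`PP_shared + PP_distinct > 0.5`, i.e. both traits do associate at the
locus) and *ratio* (`PP_shared/(PP_shared+PP_distinct) > 0.5`); both must
pass for a colocalisation-supported call, while a dominant `PP_distinct`
flags likely genetic confounding. Cytokine–cytokine colocalisation is
evaluated at the exposure cytokine's gene window (± 500 kb), the locus
where its instruments live. Multi-causal-variant (SuSiE-style) and
conditional approaches are out of scope.

## Pipeline, multiplicity and the network

Each direction applies a Bonferroni family correction for its number of
outcomes: `0.05/47 = 0.0011` with 47 cytokine outcomes and
`0.05/15 = 0.0033` with 15 cardiometabolic outcomes, computed by
`bonferroni_threshold()` from whatever family sizes are configured.
Direction-3 families are per instrument criterion, since the criteria are
reported as separate analyses. Colocalisation gates differ by design:
direction 2 colocalises family-significant pairs, direction 3 any pair
with nominal `p < 0.05`.

The cytokine graph keeps only family-significant directed edges. The
"community structure" of the network is obtained by greedy modularity
maximisation (`igraph::cluster_fast_greedy`) on the undirected projection
with `|beta|` weights, parallel edges collapsed to their maximum — a
deterministic, dependency-light choice among the many community
algorithms that fit an unspecified "network community structure" step;
the igraph object is returned so users can substitute another. Pearson
correlation between main-method betas of pairs analysed under both cis
criteria (`compare_criteria()`) quantifies criterion agreement.

Exposure-outcome pairs that fail (no instruments, empty harmonised
intersection, zero exposure betas) are skipped and logged in a `skipped`
attribute, never fatal. Reruns with identical configuration and seeds are
byte-identical: every stochastic component (bootstrap, PRESSO
simulations, simulation studies) draws through an explicit seed.

## Validation studies and their conditions

The replicated studies in `R/studies.R` fix the package's study
conditions; the acceptance script re-runs them from scratch and the test
suite asserts their outcomes. Problem sizes were chosen as the smallest
at which the asymptotic behaviour under test is expected to hold cleanly:

* **IVW coverage** — 500 two-sample replicates, 10 valid instruments with
  per-allele effects spread over 0.15–0.35, true effect 0.2, exposure and
  outcome cohorts of n = 10 000 on a shared panel; the 95% CI should
  cover the truth in 93–97% of replicates.
* **PRESSO null calibration** — 500 summary-level replicates without
  pleiotropy; global-test rejection at 0.05 should sit in [0.02, 0.08].
* **Outlier detection** — one of 10 instruments shifted by 10 outcome
  SEs; detection expected in ≥ 90% of 200 replicates.
* **Weighted-median robustness** — 40% of instruments given directional
  pleiotropy of 0.3 on the outcome scale. Instruments are equal-strength
  here so invalid instruments carry exactly 40% of weight: the study
  targets the weighted median's validity condition (valid weight ≥ 50%),
  which unequal strengths would violate sporadically for reasons
  unrelated to the estimator. Weighted-median |bias| should undercut IVW
  |bias| in ≥ 90% of replicates.
* **Colocalisation discrimination** — 40-variant loci, AR(1) block LD
  with rho 0.8, causal effects of 0.5 SD, GWAS n = 10 000; shared-variant
  loci should pass both rules and distinct-variant loci should favour H3,
  each in ≥ 80% of 200 replicates.
* **Cascade recovery** — cohorts of n = 5000 with cytokine A driven by
  one cis variant (0.5 per allele) and raising cytokine B by 0.5 SD; the
  full direction-2 pipeline should report a significant,
  colocalisation-supported A→B edge in ≥ 80% of 100 replicates.
* **Global-null family calibration** — 200 direction-1 replicates
  (n = 3000, two instrumented risk traits, six null cytokines); the
  fraction of significant rows should not exceed twice the family
  threshold.

## Known limitations

* The generator's clean additive, ancestry-free genetics means these
  results certify internal statistical correctness, not performance on
  real consortium data with imputation error, sample overlap, or
  population structure.
* The ratio SE ignores exposure uncertainty; weak-instrument settings
  (low F) will understate uncertainty, and no weak-instrument correction
  is applied.
* Binary-trait GWAS has no separation-robust (Firth) fallback.
* Single-causal-variant colocalisation can be misled by multi-signal
  loci; `passes_support` failing with strong marginal signals is the
  symptom to watch for.
* Multivariable MR, Steiger filtering and mode-based estimators are
  deliberately outside the package's scope.
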