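# Replicated simulation studies validating the estimator suite under known
# ground truth. Each study fixes its own conditions (sample sizes, effect
# sizes, instrument counts) and varies only the seed, so both the test
# suite and the acceptance script measure the same quantities.

# Shared two-sample design: 10 instruments with per-allele exposure effects
# spread over [0.15, 0.35], exposure noise SD 1, outcome = true_beta x
# exposure liability plus unit noise.
two_sample_betas <- function(n_snp = 10L) seq(0.15, 0.35, length.out = n_snp)

# One two-sample replicate from the cohort simulator: returns the
# harmonised exposure/outcome set over the instrument panel.
two_sample_replicate <- function(n = 10000L, true_beta = 0.2, seed = 1L,
                                 n_snp = 10L) {
  b <- two_sample_betas(n_snp)
  causal <- tibble::tibble(trait_id = "X", variant = seq_len(n_snp),
                           beta = b)
  traits <- tibble::tibble(
    trait_id = c("X", "Y"), type = "quantitative", noise_sd = 1,
    prevalence = NA_real_)
  dag <- tibble::tibble(from = "X", to = "Y", beta = true_beta)
  cfg_exp <- sim_config(n, n_snp, ld_rho = 0, maf_range = c(0.1, 0.5),
                        traits = traits[1, ], causal_map = causal,
                        seed = seed * 2L, panel_seed = 99L)
  cfg_out <- sim_config(n, n_snp, ld_rho = 0, maf_range = c(0.1, 0.5),
                        traits = traits, causal_map = causal,
                        trait_dag = dag, seed = seed * 2L + 1L,
                        panel_seed = 99L)
  gx <- run_gwas(simulate_cohort(cfg_exp), "X")
  gy <- run_gwas(simulate_cohort(cfg_out), "Y")
  harmonise(gx, gy)
}

#' IVW coverage under valid instruments
#'
#' Replicated two-sample MR with 10 valid instruments and a true causal
#' effect of 0.2: independent exposure and outcome cohorts of `n`
#' individuals are simulated on a shared panel, per-variant GWAS run on
#' each, and the IVW 95% confidence interval checked for covering the true
#' effect.
#'
#' @param n_reps Number of replicates (default 500).
#' @param n GWAS sample size per cohort (default 10000).
#' @param true_beta True causal effect (default 0.2).
#' @param seed Base seed.
#' @return List with `coverage_pct` (percentage of replicates whose CI
#'   covers `true_beta`) and `n_reps`.
#' @export
study_ivw_coverage <- function(n_reps = 500L, n = 10000L, true_beta = 0.2,
                               seed = 1L) {
  covered <- vapply(seq_len(n_reps), function(r) {
    h <- two_sample_replicate(n = n, true_beta = true_beta,
                              seed = seed * 100000L + r)
    fit <- mr_ivw(h)
    fit$ci_low <= true_beta && fit$ci_high >= true_beta
  }, logical(1))
  list(coverage_pct = 100 * mean(covered), n_reps = n_reps)
}

# Summary-statistic-level replicate: draws estimated effects around the
# truth without a cohort, for estimator-level calibration studies.
summary_replicate <- function(true_beta = 0.2, n_snp = 10L, sex = 0.02,
                              sey = 0.04, pleio = rep(0, n_snp),
                              b = two_sample_betas(n_snp)) {
  bx <- rnorm(n_snp, b, sex)
  by <- rnorm(n_snp, true_beta * b + pleio, sey)
  harmonised_set(bx, rep(sex, n_snp), by, rep(sey, n_snp))
}

#' MR-PRESSO global-test calibration under no pleiotropy
#'
#' Replicated summary-level two-sample MR with 10 valid instruments (true
#' effect 0.2, no pleiotropy): the MR-PRESSO global test should reject at
#' close to its nominal 5% rate.
#'
#' @param n_reps Number of replicates (default 500).
#' @param n_sim PRESSO simulations per replicate (default 1000).
#' @param seed Base seed.
#' @return List with `rejection_rate` (fraction of replicates with global
#'   p < 0.05) and `n_reps`.
#' @export
study_presso_null <- function(n_reps = 500L, n_sim = 1000L, seed = 1L) {
  rej <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      h <- summary_replicate()
      cfg <- mr_config(n_sim = n_sim,
                       seed = sample.int(.Machine$integer.max, 1))
      mr_presso(h, cfg)$extras$presso_global_p < 0.05
    }, logical(1))
  })
  list(rejection_rate = mean(rej), n_reps = n_reps)
}

#' MR-PRESSO detection of an injected outlier
#'
#' One of 10 instruments receives an outcome shift of 10 standard errors;
#' the study measures how often MR-PRESSO flags exactly that variant as an
#' outlier.
#'
#' @param n_reps Number of replicates (default 200).
#' @param n_sim PRESSO simulations per replicate.
#' @param shift_se Outlier shift in units of the outcome standard error
#'   (default 10).
#' @param seed Base seed.
#' @return List with `detection_rate` and `n_reps`.
#' @export
study_presso_outlier <- function(n_reps = 200L, n_sim = 1000L,
                                 shift_se = 10, seed = 1L) {
  n_snp <- 10L
  sey <- 0.04
  hits <- withr::with_seed(seed, {
    vapply(seq_len(n_reps), function(r) {
      pleio <- rep(0, n_snp)
      pleio[1] <- shift_se * sey
      h <- summary_replicate(pleio = pleio)
      cfg <- mr_config(n_sim = n_sim,
                       seed = sample.int(.Machine$integer.max, 1))
      "v1" %in% mr_presso(h, cfg)$extras$presso_outliers
    }, logical(1))
  })
  list(detection_rate = mean(hits), n_reps = n_reps)
}

#' Weighted-median robustness against directional pleiotropy
#'
#' With 40% of the 10 instruments given a directional (all-positive)
#' pleiotropic effect of 0.3 on the outcome scale, the weighted median
#' should show smaller absolute bias than IVW in nearly all replicates,
#' since instruments carrying a majority of the weight remain valid. The
#' instruments have equal strength here so that the invalid 40% of
#' instruments carry 40% of the weight: the weighted median's validity
#' condition (valid instruments hold at least half the weight) is what the
#' study exercises, so the design must satisfy it.
#'
#' @param n_reps Number of replicates (default 200).
#' @param pleio_frac Fraction of pleiotropic instruments (default 0.4).
#' @param pleio_effect Direct outcome effect of each invalid instrument
#'   (default 0.3).
#' @param seed Base seed.
#' @return List with `wm_wins_rate` (fraction of replicates where the
#'   weighted-median absolute bias is below the IVW absolute bias),
#'   `mean_abs_bias_wm`, `mean_abs_bias_ivw` and `n_reps`.
#' @export
study_wm_robustness <- function(n_reps = 200L, pleio_frac = 0.4,
                                pleio_effect = 0.3, seed = 1L) {
  n_snp <- 10L
  true_beta <- 0.2
  n_pleio <- round(pleio_frac * n_snp)
  res <- withr::with_seed(seed, {
    t(vapply(seq_len(n_reps), function(r) {
      pleio <- rep(0, n_snp)
      pleio[sample.int(n_snp, n_pleio)] <- pleio_effect
      h <- summary_replicate(pleio = pleio, b = rep(0.25, n_snp))
      ivw_b <- mr_ivw(h)$beta
      wm_b <- weighted_median_point(h$beta_out / h$beta_exp,
                                    h$beta_exp^2 / h$se_out^2)
      c(abs(wm_b - true_beta), abs(ivw_b - true_beta))
    }, numeric(2)))
  })
  list(wm_wins_rate = mean(res[, 1] < res[, 2]),
       mean_abs_bias_wm = mean(res[, 1]),
       mean_abs_bias_ivw = mean(res[, 2]),
       n_reps = n_reps)
}

# One colocalisation replicate: two cohorts on a shared 40-variant panel
# with block LD; trait 1 causal at variant 15 and trait 2 either at the
# same variant (shared) or at variant 35 in a different LD block
# (distinct). Effects are 0.5 SD, GWAS n individuals per cohort.
coloc_replicate <- function(shared, n = 10000L, effect = 0.5, seed = 1L) {
  m <- 40L
  v2 <- if (shared) 15L else 35L
  mk <- function(trait, variant, s) {
    sim_config(n, m, ld_block_size = 10L, ld_rho = 0.8,
               maf_range = c(0.1, 0.5),
               traits = tibble::tibble(trait_id = trait,
                                       type = "quantitative",
                                       noise_sd = 1, prevalence = NA_real_),
               causal_map = tibble::tibble(trait_id = trait,
                                           variant = variant,
                                           beta = effect),
               seed = s, panel_seed = 7L)
  }
  g1 <- run_gwas(simulate_cohort(mk("T1", 15L, seed * 2L)), "T1")
  g2 <- run_gwas(simulate_cohort(mk("T2", v2, seed * 2L + 1L)), "T2")
  h <- harmonise(g1, g2)
  suppressWarnings(colocalise(
    tibble::tibble(variant_id = h$variant_id, beta = h$beta_exp,
                   se = h$se_exp),
    tibble::tibble(variant_id = h$variant_id, beta = h$beta_out,
                   se = h$se_out)))
}

#' Colocalisation discrimination between shared and distinct causal variants
#'
#' Loci simulated with a single causal variant shared by both traits should
#' pass both posterior decision rules; loci where the two traits' causal
#' variants sit in different LD blocks (linkage equilibrium) should favour
#' the distinct-variants hypothesis.
#'
#' @param n_reps Replicates per scenario (default 200).
#' @param n GWAS sample size per cohort (default 10000).
#' @param effect Causal effect in SD units (default 0.5).
#' @param seed Base seed.
#' @return List with `shared_pass_rate` (fraction of shared-variant loci
#'   passing both rules), `distinct_rate` (fraction of distinct-variant
#'   loci with `pp_distinct > pp_shared`) and `n_reps`.
#' @export
study_coloc_discrimination <- function(n_reps = 200L, n = 10000L,
                                       effect = 0.5, seed = 1L) {
  shared_pass <- vapply(seq_len(n_reps), function(r) {
    cl <- coloc_replicate(TRUE, n = n, effect = effect,
                          seed = seed * 100000L + r)
    cl$passes_support && cl$passes_ratio
  }, logical(1))
  distinct <- vapply(seq_len(n_reps), function(r) {
    cl <- coloc_replicate(FALSE, n = n, effect = effect,
                          seed = seed * 100000L + 50000L + r)
    cl$pp_distinct > cl$pp_shared
  }, logical(1))
  list(shared_pass_rate = mean(shared_pass),
       distinct_rate = mean(distinct), n_reps = n_reps)
}

#' End-to-end recovery of a simulated cytokine cascade
#'
#' Simulates a cohort where cytokine A has one cis causal variant (0.5 per
#' allele) and causally raises cytokine B (effect 0.5 SD), runs the full
#' direction-2 pipeline (cis-pQTL instrument selection, MR, colocalisation
#' at the exposure locus, network construction) and measures how often the
#' A-to-B edge is recovered as significant and colocalisation-supported.
#'
#' @param n_reps Number of pipeline replicates (default 100).
#' @param n Cohort size (default 5000).
#' @param seed Base seed.
#' @return List with `recovery_rate` and `n_reps`.
#' @export
study_cascade_recovery <- function(n_reps = 100L, n = 5000L, seed = 1L) {
  m <- 60L
  causal_variant <- 15L
  # 50 kb variant spacing keeps the two gene windows disjoint, so B's
  # locus cannot borrow A's causal variant as a cis instrument
  loci <- dplyr::bind_rows(
    gene_locus("A", "1", 749000, 751000),
    gene_locus("B", "1", 2499000, 2501000))
  traits <- tibble::tibble(
    trait_id = c("A", "B"), type = "cytokine", noise_sd = 1,
    prevalence = NA_real_)
  recovered <- vapply(seq_len(n_reps), function(r) {
    cfg <- sim_config(
      n, m, ld_block_size = 10L, ld_rho = 0.6, maf_range = c(0.1, 0.5),
      traits = traits,
      causal_map = tibble::tibble(trait_id = "A",
                                  variant = causal_variant, beta = 0.5),
      trait_dag = tibble::tibble(from = "A", to = "B", beta = 0.5),
      gene_loci = loci, pos_spacing = 50000L, seed = seed * 100000L + r)
    cohort <- simulate_cohort(cfg)
    ga <- run_gwas(cohort, "A")
    gb <- run_gwas(cohort, "B")
    ld <- ld_from_dosages(cohort$dosages)
    d2 <- run_direction_2(list(ga, gb), ld, loci,
                          config = pipeline_config(
                            mr = mr_config(seed = seed * 100000L + r)))
    e <- d2$graph$edges
    any(e$exposure == "A" & e$outcome == "B" & e$coloc_supported)
  }, logical(1))
  list(recovery_rate = mean(recovered), n_reps = n_reps)
}

#' False-positive calibration of a global-null pipeline family
#'
#' Risk traits have real genetic architecture (so instruments are
#' selectable) but zero causal effect on any cytokine; across replicates
#' the fraction of direction-1 rows flagged significant should not exceed
#' about its Bonferroni family bound.
#'
#' @param n_reps Number of replicates (default 200).
#' @param n Cohort size per sample (default 3000).
#' @param seed Base seed.
#' @return List with `fp_rate` (fraction of rows significant),
#'   `bound` (the family threshold `alpha / n_cytokines`), `n_rows`
#'   (total rows over all replicates) and `n_reps`.
#' @export
study_null_family <- function(n_reps = 200L, n = 3000L, seed = 1L) {
  m <- 40L
  n_cyt <- 6L
  risk_causal <- dplyr::bind_rows(
    tibble::tibble(trait_id = "R1", variant = seq(1L, 29L, by = 4L),
                   beta = 0.25),
    tibble::tibble(trait_id = "R2", variant = seq(3L, 31L, by = 4L),
                   beta = 0.25))
  risk_traits <- tibble::tibble(
    trait_id = c("R1", "R2"), type = "quantitative", noise_sd = 1,
    prevalence = NA_real_)
  cyt_traits <- tibble::tibble(
    trait_id = paste0("C", seq_len(n_cyt)), type = "cytokine",
    noise_sd = 1, prevalence = NA_real_)
  counts <- vapply(seq_len(n_reps), function(r) {
    cfg_r <- sim_config(n, m, ld_rho = 0, maf_range = c(0.1, 0.5),
                        traits = risk_traits, causal_map = risk_causal,
                        seed = seed * 100000L + 2L * r, panel_seed = 11L)
    cfg_c <- sim_config(n, m, ld_rho = 0, maf_range = c(0.1, 0.5),
                        traits = cyt_traits,
                        seed = seed * 100000L + 2L * r + 1L,
                        panel_seed = 11L)
    coh_r <- simulate_cohort(cfg_r)
    coh_c <- simulate_cohort(cfg_c)
    risk <- lapply(c("R1", "R2"), function(t) run_gwas(coh_r, t))
    cyts <- lapply(cyt_traits$trait_id, function(t) run_gwas(coh_c, t))
    ld <- ld_from_dosages(coh_r$dosages)
    # the family flag uses only the main (IVW) p-value, so the sensitivity
    # estimators' bootstrap/simulation sizes are kept at their minimum
    rows <- run_direction_1(risk, cyts, ld,
                            config = pipeline_config(
                              mr = mr_config(n_boot = 100L, n_sim = 100L,
                                             seed = seed * 100000L + r)))
    c(sig = sum(rows$significant), total = nrow(rows))
  }, numeric(2))
  total <- sum(counts["total", ])
  list(fp_rate = sum(counts["sig", ]) / total,
       bound = bonferroni_threshold(0.05, n_cyt),
       n_rows = total, n_reps = n_reps)
}
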