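quant_traits <- function(ids, noise_sd = 1, type = "quantitative") {
  tibble::tibble(trait_id = ids, type = type, noise_sd = noise_sd,
                 prevalence = NA_real_)
}

test_that("simulation is byte-reproducible under a fixed seed", {
  cfg <- sim_config(200, 30, ld_rho = 0.5, traits = quant_traits("T"),
                    causal_map = tibble::tibble(trait_id = "T", variant = 3L,
                                                beta = 0.4),
                    seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$phenotypes, b$phenotypes)
})

test_that("ld_rho = 0 gives empirically independent variants", {
  cfg <- sim_config(4000, 20, ld_rho = 0, seed = 11)
  coh <- simulate_cohort(cfg)
  r <- ld_from_dosages(coh$dosages)
  off <- abs(r[upper.tri(r)])
  expect_lte(mean(off), 2 / sqrt(cfg$n_individuals))
})

test_that("empirical LD tracks the configured rho^distance decay", {
  cfg <- sim_config(6000, 20, ld_block_size = 10, ld_rho = 0.8,
                    maf_range = c(0.2, 0.5), seed = 5)
  coh <- simulate_cohort(cfg)
  r <- ld_from_dosages(coh$dosages)
  # dosage correlation is attenuated relative to the latent AR(1), but
  # adjacent pairs must be strongly correlated and decay with distance
  adj <- mean(abs(r[cbind(1:9, 2:10)]))
  far <- mean(abs(r[cbind(1:5, 6:10)]))
  expect_gt(adj, far)
  expect_gt(adj, 0.5)
  # across blocks: independent
  expect_lt(mean(abs(r[1:10, 11:20])), 0.05)
})

test_that("a trait with no causal variants is pure noise with the set SD", {
  cfg <- sim_config(5000, 5, traits = quant_traits("null_trait"), seed = 2)
  coh <- simulate_cohort(cfg)
  expect_lt(abs(var(coh$phenotypes$null_trait) - 1), 0.1)
})

test_that("a trait DAG edge is recovered by regression on the parent", {
  cfg <- sim_config(5000, 5, traits = quant_traits(c("A", "B")),
                    trait_dag = tibble::tibble(from = "A", to = "B",
                                               beta = 0.5),
                    seed = 3)
  coh <- simulate_cohort(cfg)
  fit <- summary(lm(coh$phenotypes$B ~ coh$phenotypes$A))
  est <- fit$coefficients[2, 1]
  se <- fit$coefficients[2, 2]
  expect_lt(abs(est - 0.5), 3 * se)
})

test_that("binary traits hit the configured prevalence", {
  traits <- tibble::tibble(trait_id = "D", type = "binary", noise_sd = 1,
                           prevalence = 0.2)
  cfg <- sim_config(5000, 5, traits = traits, seed = 4)
  coh <- simulate_cohort(cfg)
  expect_equal(mean(coh$phenotypes$D), 0.2, tolerance = 0.01)
})

test_that("a causal index out of range is a hard error", {
  expect_error(
    sim_config(100, 5, traits = quant_traits("T"),
               causal_map = tibble::tibble(trait_id = "T", variant = 9L,
                                           beta = 1)),
    "out of range")
})

test_that("expression has tissue-shared cis signal", {
  em <- tibble::tibble(gene = "G1", variant = 2L, beta_shared = 0.8,
                       beta_tissue_sd = 0.1)
  cfg <- sim_config(3000, 5, expression_map = em, n_tissues = 3, seed = 6)
  coh <- simulate_cohort(cfg)
  expect_equal(dim(coh$expression$G1), c(3000, 3))
  for (t in 1:3) {
    r <- cor(coh$expression$G1[, t], coh$dosages[2, ])
    expect_gt(r, 0.2)
  }
})

test_that("inverse normal transform matches the Blom formula and its properties", {
  # symmetric three-point case: ranks 1,2,3 of m=3
  got <- inverse_normal_transform(c(1, 2, 3))
  expect_equal(got[2], 0)
  expect_equal(got[1], -got[3])
  expect_equal(got[1], qnorm((1 - 0.375) / 3.25))
  # rank preservation and near-zero mean
  set.seed(9)
  x <- rnorm(1000)
  y <- inverse_normal_transform(x)
  expect_identical(order(x), order(y))
  expect_lt(abs(mean(y)), 1e-8)
  # strong agreement with already-normal input
  expect_gt(cor(x, y), 0.99)
  # ties share the average rank
  expect_equal(inverse_normal_transform(c(1, 1, 2))[1],
               inverse_normal_transform(c(1, 1, 2))[2])
  expect_error(inverse_normal_transform(rep(1, 10)), "constant")
  expect_error(inverse_normal_transform(1), "at least 2")
})

test_that("run_gwas equals closed-form OLS (lm) per variant", {
  cfg <- sim_config(400, 6, traits = quant_traits("T"),
                    causal_map = tibble::tibble(trait_id = "T",
                                                variant = 1L, beta = 0.5),
                    seed = 12)
  coh <- simulate_cohort(cfg)
  ss <- run_gwas(coh, "T")
  for (j in 1:6) {
    fit <- summary(lm(coh$phenotypes$T ~ coh$dosages[j, ]))
    expect_equal(ss$beta[j], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(ss$se[j], fit$coefficients[2, 2], tolerance = 1e-10)
  }
  expect_equal(ss$eaf, rowMeans(coh$dosages) / 2)
})

test_that("run_gwas with covariates equals multiple-regression lm", {
  cfg <- sim_config(300, 3, traits = quant_traits("T"), seed = 13)
  coh <- simulate_cohort(cfg)
  covar <- cbind(rnorm(300), rnorm(300))
  ss <- run_gwas(coh, "T", covariates = covar)
  for (j in 1:3) {
    fit <- summary(lm(coh$phenotypes$T ~ coh$dosages[j, ] + covar))
    expect_equal(ss$beta[j], fit$coefficients[2, 1], tolerance = 1e-10)
    expect_equal(ss$se[j], fit$coefficients[2, 2], tolerance = 1e-10)
  }
})

test_that("binary-trait GWAS equals logistic glm", {
  traits <- tibble::tibble(trait_id = "D", type = "binary", noise_sd = 1,
                           prevalence = 0.3)
  cfg <- sim_config(500, 3, traits = traits,
                    causal_map = tibble::tibble(trait_id = "D",
                                                variant = 1L, beta = 0.4),
                    seed = 14)
  coh <- simulate_cohort(cfg)
  ss <- run_gwas(coh, "D")
  for (j in 1:3) {
    fit <- summary(glm(coh$phenotypes$D ~ coh$dosages[j, ],
                       family = binomial()))
    expect_equal(ss$beta[j], fit$coefficients[2, 1], tolerance = 1e-6)
    expect_equal(ss$se[j], fit$coefficients[2, 2], tolerance = 1e-6)
  }
})

test_that("null GWAS p-values are calibrated", {
  cfg <- sim_config(800, 1000, traits = quant_traits("T"), seed = 15)
  coh <- simulate_cohort(cfg)
  ss <- run_gwas(coh, "T")
  frac <- mean(ss$p < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.07)
  expect_true(all(abs(ss$beta / ss$se) < 6))
})

test_that("monomorphic variants are flagged with infinite se", {
  cfg <- sim_config(100, 3, maf_range = c(0.4, 0.5),
                    traits = quant_traits("T"), seed = 16)
  coh <- simulate_cohort(cfg)
  coh$dosages[2, ] <- 0
  ss <- run_gwas(coh, "T")
  expect_equal(ss$beta[2], 0)
  expect_equal(ss$se[2], Inf)
  expect_equal(ss$p[2], 1)
})

test_that("GWAS recovers a simulated true effect within 4 se", {
  hits <- vapply(1:30, function(r) {
    cfg <- sim_config(1500, 4, ld_rho = 0, traits = quant_traits("T"),
                      causal_map = tibble::tibble(trait_id = "T",
                                                  variant = 2L, beta = 0.3),
                      seed = 100 + r)
    ss <- run_gwas(simulate_cohort(cfg), "T")
    abs(ss$beta[2] - 0.3) < 4 * ss$se[2]
  }, logical(1))
  expect_gte(mean(hits), 0.99 - 1e-9)
})
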