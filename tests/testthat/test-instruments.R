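# An LD matrix with two tight pairs and independent remainder.
block_ld <- function() {
  ids <- paste0("rs", 1:6)
  r <- diag(6)
  r[1, 2] <- r[2, 1] <- 0.99
  r[3, 4] <- r[4, 3] <- 0.5
  dimnames(r) <- list(ids, ids)
  r
}

test_that("clump keeps everything when all pairwise r2 = 0", {
  ss <- toy_sumstats("t", n_var = 6, p = rep(1e-10, 6))
  kept <- clump(ss, toy_ld(ss$variant_id), r2_max = 0.001, p_max = 5e-8)
  expect_equal(sort(kept$variant_id), sort(ss$variant_id))
})

test_that("clump keeps the smaller-p member of a perfect-LD pair", {
  ss <- toy_sumstats("t", n_var = 2, p = c(1e-9, 1e-10))
  ld <- matrix(c(1, 1, 1, 1), 2,
               dimnames = list(ss$variant_id, ss$variant_id))
  kept <- clump(ss, ld, r2_max = 0.001, p_max = 5e-8)
  expect_equal(kept$variant_id, "rs2")  # p = 1e-10
})

test_that("clump equals the independent greedy oracle on mixed LD", {
  set.seed(31)
  for (rep in 1:10) {
    m <- 10
    ids <- paste0("rs", 1:m)
    a <- matrix(rnorm(m * m), m)
    r <- cov2cor(crossprod(a) + diag(m))
    dimnames(r) <- list(ids, ids)
    ss <- toy_sumstats("t", n_var = m, p = 10^-runif(m, 2, 12))
    for (r2m in c(0.001, 0.1, 0.5)) {
      got <- clump(ss, r, r2_max = r2m, p_max = 1e-3)
      want <- oracle_clump(tibble::as_tibble(ss), r, r2m, 1e-3)
      expect_equal(got$variant_id, want$variant_id)
    }
  }
})

test_that("clump output is invariant to input order and is deterministic", {
  ss <- toy_sumstats("t", n_var = 6, p = c(1e-10, 1e-10, 1e-9, 1e-8,
                                           1e-7, 1e-6))
  ld <- block_ld()
  a <- clump(ss, ld, 0.3, 1e-5)
  b <- clump(ss[sample(6), ], ld, 0.3, 1e-5)
  expect_equal(a$variant_id, b$variant_id)
})

test_that("clump errors when a candidate is missing from the LD reference", {
  ss <- toy_sumstats("t", n_var = 3, p = rep(1e-10, 3))
  ld <- toy_ld(ss$variant_id[1:2])
  expect_error(clump(ss, ld), "rs3")
})

test_that("trait instrument selection applies strict thresholds", {
  ss <- toy_sumstats("bmi", n_var = 3, p = c(4e-8, 5e-8, 1e-9))
  instr <- select_trait_instruments(ss, toy_ld(ss$variant_id))
  # p = 5e-8 exactly fails the strict p < 5e-8 rule
  expect_setequal(instr$variant_id, c("rs1", "rs3"))
  expect_equal(criterion(instr), "trait_gwas")

  # the fasting-insulin convention relaxes the threshold to 1e-6
  fi <- toy_sumstats("fasting_insulin", n_var = 2, p = c(5e-7, 5e-5))
  instr_fi <- select_trait_instruments(fi, toy_ld(fi$variant_id),
                                       p_max = 1e-6)
  expect_equal(instr_fi$variant_id, "rs1")
})

test_that("a null trait yields an empty set with a warning", {
  ss <- toy_sumstats("null", n_var = 10, p = runif(10, 0.1, 1))
  expect_warning(instr <- select_trait_instruments(ss, toy_ld(ss$variant_id)),
                 "no instruments")
  expect_equal(nrow(instr), 0)
})

test_that("cis windows are inclusive at exactly +/- window", {
  locus <- gene_locus("CYT", "1", 600000, 601000)
  ss <- toy_sumstats("CYT", n_var = 3,
                     pos = c(100000L, 99999L, 1101000L),
                     p = rep(1e-6, 3))
  instr <- select_cis_pqtl(ss, locus, toy_ld(ss$variant_id),
                           window = 500000L)
  # pos 100000 = start - window exactly (in), 99999 is out,
  # 1101000 = end + window exactly (in)
  expect_setequal(instr$variant_id, c("rs1", "rs3"))
  expect_equal(criterion(instr), "cis_pqtl")
})

test_that("cis-pQTL selection applies the 1e-4 cytokine threshold", {
  locus <- gene_locus("CYT", "1", 1000, 5000)
  ss <- toy_sumstats("CYT", n_var = 2, p = c(2e-4, 5e-5))
  instr <- select_cis_pqtl(ss, locus, toy_ld(ss$variant_id))
  expect_equal(instr$variant_id, "rs2")
})

test_that("cis-eQTL selection requires both expression and cytokine evidence", {
  locus <- gene_locus("CYT", "1", 1000, 5000)
  cyt <- toy_sumstats("CYT", n_var = 3, p = c(0.04, 0.2, 0.04))
  expr <- toy_sumstats("CYT", n_var = 3, p = c(1e-5, 1e-5, 2e-4))
  ld <- toy_ld(cyt$variant_id)
  instr <- select_cis_eqtl(cyt, expr, locus, ld)
  # rs1: expr 1e-5 & cyt 0.04 -> in; rs2 fails cytokine; rs3 fails expression
  expect_equal(instr$variant_id, "rs1")
  expect_equal(criterion(instr), "cis_eqtl")
  # exposure betas come from the cytokine statistics
  expect_equal(instr$beta, cyt$beta[1])
})

test_that("genome-wide cytokine selection admits trans signals cis criteria drop", {
  locus <- gene_locus("CYT", "1", 1000, 2000)
  ss <- toy_sumstats("CYT", n_var = 2,
                     pos = c(1500L, 900000000L), p = c(1e-6, 1e-9))
  ld <- toy_ld(ss$variant_id)
  gw <- select_genomewide_cytokine(ss, ld)
  expect_equal(gw$variant_id, "rs2")       # trans variant, p < 5e-8
  cis <- select_cis_pqtl(ss, locus, ld)
  expect_equal(cis$variant_id, "rs1")      # trans variant outside window
  expect_equal(criterion(gw), "genomewide_cytokine")
})

test_that("shrinking window or threshold never adds instruments", {
  set.seed(77)
  locus <- gene_locus("CYT", "1", 40000, 60000)
  ss <- toy_sumstats("CYT", n_var = 50,
                     pos = as.integer(seq(1000, 200000, length.out = 50)),
                     p = 10^-runif(50, 1, 8))
  ld <- toy_ld(ss$variant_id)
  for (w in list(c(1e5, 5e4), c(5e4, 1e4))) {
    a <- select_cis_pqtl(ss, locus, ld, window = w[1])
    b <- select_cis_pqtl(ss, locus, ld, window = w[2])
    expect_true(all(b$variant_id %in% a$variant_id))
  }
  for (p in list(c(1e-2, 1e-4), c(1e-4, 1e-6))) {
    a <- select_cis_pqtl(ss, locus, ld, window = 1e5, p_max = p[1])
    b <- select_cis_pqtl(ss, locus, ld, window = 1e5, p_max = p[2])
    expect_true(all(b$variant_id %in% a$variant_id))
  }
})

test_that("retained instruments satisfy pairwise r2 below the ceiling", {
  set.seed(78)
  m <- 12
  ids <- paste0("rs", 1:m)
  a <- matrix(rnorm(m * m), m)
  r <- cov2cor(crossprod(a) + 0.5 * diag(m))
  dimnames(r) <- list(ids, ids)
  ss <- toy_sumstats("t", n_var = m, p = 10^-runif(m, 4, 10))
  kept <- clump(ss, r, r2_max = 0.2, p_max = 1e-3)
  if (nrow(kept) > 1) {
    sub <- r[kept$variant_id, kept$variant_id]^2
    expect_true(all(sub[upper.tri(sub)] < 0.2))
  }
})

test_that("a simulated cis signal is recovered as the instrument", {
  hits <- vapply(1:20, function(r) {
    cfg <- sim_config(5000, 20, ld_block_size = 5, ld_rho = 0.7,
                      maf_range = c(0.1, 0.5),
                      traits = tibble::tibble(trait_id = "CYT",
                                              type = "cytokine",
                                              noise_sd = 1,
                                              prevalence = NA_real_),
                      causal_map = tibble::tibble(trait_id = "CYT",
                                                  variant = 8L, beta = 0.3),
                      pos_spacing = 1000L, seed = 500 + r)
    coh <- simulate_cohort(cfg)
    ss <- run_gwas(coh, "CYT")
    ld <- ld_from_dosages(coh$dosages)
    locus <- gene_locus("CYT", "1", 7500, 8500)
    instr <- select_cis_pqtl(ss, locus, ld, window = 500000L)
    if (nrow(instr) == 0) return(FALSE)
    any(ld["rs8", instr$variant_id]^2 >= 0.8 | instr$variant_id == "rs8")
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
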