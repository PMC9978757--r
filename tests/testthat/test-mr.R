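test_that("wald ratio arithmetic, sign handling and guards", {
  h <- harmonised_set(1, 0.1, 0.2, 0.05)
  r <- wald_ratio(h)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.05)
  expect_equal(r$ci_low, 0.2 - 1.96 * 0.05)
  expect_equal(r$ci_high, 0.2 + 1.96 * 0.05)

  r2 <- wald_ratio(harmonised_set(0.5, 0.1, 0.25, 0.05))
  expect_equal(r2$beta, 0.5)
  expect_equal(r2$se, 0.1)

  r3 <- wald_ratio(harmonised_set(-0.5, 0.1, 0.25, 0.05))
  expect_equal(r3$beta, -0.5)
  expect_equal(r3$se, 0.1)

  expect_error(wald_ratio(harmonised_set(c(1, 1), c(0.1, 0.1),
                                         c(0.2, 0.2), c(0.05, 0.05))),
               "exactly 1")
  expect_error(wald_ratio(harmonised_set(0, 0.1, 0.2, 0.05)), "zero")
})

test_that("ivw on replicate instruments: Q = 0, se = se/sqrt(2)", {
  h <- harmonised_set(c(1, 1), c(0.1, 0.1), c(0.2, 0.2), c(0.1, 0.1))
  r <- mr_ivw(h)
  expect_equal(r$beta, 0.2)
  expect_equal(r$se, 0.1 / sqrt(2))
  expect_equal(r$extras$Q, 0)
})

test_that("ivw of a duplicated single variant equals the wald ratio", {
  h1 <- harmonised_set(0.4, 0.05, 0.12, 0.03)
  h2 <- harmonised_set(c(0.4, 0.4), c(0.05, 0.05), c(0.12, 0.12),
                       c(0.03, 0.03))
  expect_equal(mr_ivw(h2)$beta, wald_ratio(h1)$beta)
})

test_that("ivw equals the WLS-through-origin oracle to 1e-12", {
  set.seed(41)
  for (rep in 1:5) {
    m <- 5
    h <- harmonised_set(runif(m, 0.1, 0.5), runif(m, 0.01, 0.1),
                        rnorm(m, 0.1, 0.2), runif(m, 0.02, 0.2))
    r <- mr_ivw(h)
    fit <- lm(h$beta_out ~ h$beta_exp - 1, weights = 1 / h$se_out^2)
    expect_equal(r$beta, unname(coef(fit)), tolerance = 1e-12)
    # fixed-effect se from the weighted design, inflated when Q > df
    w <- 1 / h$se_out^2
    q <- sum(w * (h$beta_out - r$beta * h$beta_exp)^2)
    se_fe <- 1 / sqrt(sum(w * h$beta_exp^2))
    expect_equal(r$se, se_fe * sqrt(max(1, q / (m - 1))), tolerance = 1e-12)
  }
})

test_that("ivw requires at least 2 variants", {
  expect_error(mr_ivw(harmonised_set(1, 0.1, 0.2, 0.05)), "wald_ratio")
})

test_that("weighted median: unweighted case hits the middle ratio", {
  h <- harmonised_set(c(1, 1, 1), c(0.01, 0.01, 0.01),
                      c(0.1, 0.2, 0.9), c(0.05, 0.05, 0.05))
  r <- mr_weighted_median(h, mr_config(seed = 1))
  expect_equal(r$beta, 0.2)
})

test_that("weighted median is degenerate-safe: equal ratios return c", {
  h <- harmonised_set(c(0.2, 0.4, 0.8), c(0.01, 0.01, 0.01),
                      c(0.2, 0.4, 0.8) * 0.37, c(0.02, 0.09, 0.01))
  r <- mr_weighted_median(h, mr_config(seed = 1))
  expect_equal(r$beta, 0.37)
})

test_that("weighted median equals the interpolation oracle; bootstrap is seeded", {
  set.seed(43)
  for (rep in 1:5) {
    m <- 7
    h <- harmonised_set(runif(m, 0.1, 0.6), runif(m, 0.01, 0.05),
                        rnorm(m, 0.15, 0.3), runif(m, 0.02, 0.2))
    r <- mr_weighted_median(h, mr_config(seed = 10))
    want <- oracle_weighted_median(h$beta_out / h$beta_exp,
                                   h$beta_exp^2 / h$se_out^2)
    expect_equal(r$beta, want, tolerance = 1e-12)
    r2 <- mr_weighted_median(h, mr_config(seed = 10))
    expect_identical(r$se, r2$se)
    r3 <- mr_weighted_median(h, mr_config(seed = 11))
    expect_false(identical(r$se, r3$se))
  }
})

test_that("egger recovers an exact linear relation with intercept", {
  bx <- c(0.2, 0.3, 0.4, 0.5)
  by <- 0.1 + 0.3 * bx
  h <- harmonised_set(bx, rep(0.01, 4), by, c(0.05, 0.02, 0.07, 0.04))
  r <- mr_egger(h, mr_config(seed = 1))
  expect_equal(r$beta, 0.3, tolerance = 1e-10)
  expect_equal(r$extras$egger_intercept, 0.1, tolerance = 1e-10)
})

test_that("egger slope equals ivw under zero intercept and equal weights", {
  bx <- c(0.2, 0.35, 0.5)
  by <- 0.3 * bx
  h <- harmonised_set(bx, rep(0.01, 3), by, rep(0.05, 3))
  expect_equal(mr_egger(h)$beta, mr_ivw(h)$beta, tolerance = 1e-9)
})

test_that("egger matches weighted lm with orientation applied", {
  set.seed(44)
  m <- 6
  h <- harmonised_set(c(-0.3, 0.2, 0.5, -0.4, 0.25, 0.6), runif(m, 0.01, 0.05),
                      rnorm(m, 0, 0.2), runif(m, 0.02, 0.1))
  r <- mr_egger(h)
  flip <- sign(h$beta_exp)
  fit <- summary(lm(I(h$beta_out * flip) ~ I(h$beta_exp * flip),
                    weights = 1 / h$se_out^2))
  expect_equal(r$beta, fit$coefficients[2, 1], tolerance = 1e-10)
  # lm scales by sigma-hat; the estimator floors the dispersion at 1
  sigma2 <- fit$sigma^2
  want_se <- fit$coefficients[2, 2] / sqrt(sigma2) * sqrt(max(1, sigma2))
  expect_equal(r$se, want_se, tolerance = 1e-10)
})

test_that("egger recovers mean directional pleiotropy as its intercept", {
  set.seed(45)
  ints <- vapply(1:500, function(r) {
    m <- 20
    bx <- runif(m, 0.1, 0.5)
    by <- 0.05 + 0.2 * bx + rnorm(m, 0, 0.02)
    h <- harmonised_set(bx, rep(0.005, m), by, rep(0.02, m))
    mr_egger(h)$extras$egger_intercept
  }, numeric(1))
  expect_lt(abs(mean(ints) - 0.05), 0.01)
})

test_that("presso passes through ivw when no outliers are found", {
  set.seed(46)
  m <- 8
  bx <- runif(m, 0.2, 0.5)
  h <- harmonised_set(bx, rep(0.01, m), 0.2 * bx + rnorm(m, 0, 0.01),
                      rep(0.04, m))
  r <- mr_presso(h, mr_config(seed = 5))
  expect_equal(r$beta, mr_ivw(h)$beta)
  expect_equal(r$se, mr_ivw(h)$se)
  expect_length(r$extras$presso_outliers, 0)
  expect_gt(r$extras$presso_global_p, 0.05)
})

test_that("presso flags a gross outlier and reports a distorted estimate", {
  set.seed(47)
  m <- 10
  bx <- runif(m, 0.2, 0.5)
  by <- 0.2 * bx
  by[3] <- by[3] + 10 * 0.04
  h <- harmonised_set(bx, rep(0.01, m), by, rep(0.04, m))
  r <- mr_presso(h, mr_config(seed = 6))
  expect_true("v3" %in% r$extras$presso_outliers)
  expect_lt(r$extras$presso_global_p, 0.05)
  expect_equal(r$n_snp, m - length(r$extras$presso_outliers))
  expect_true(is.numeric(r$extras$presso_distortion_p))
  # outlier-removed estimate is closer to the truth than the raw one
  expect_lt(abs(r$beta - 0.2), abs(r$extras$beta_raw - 0.2))
})

test_that("presso requires at least 4 variants and is seed-reproducible", {
  h3 <- harmonised_set(1:3 / 10, rep(0.01, 3), 1:3 / 50, rep(0.04, 3))
  expect_error(mr_presso(h3), ">= 4")
  set.seed(48)
  m <- 6
  h <- harmonised_set(runif(m, 0.1, 0.5), rep(0.01, m),
                      rnorm(m, 0.05, 0.05), rep(0.04, m))
  a <- mr_presso(h, mr_config(seed = 9))
  b <- mr_presso(h, mr_config(seed = 9))
  expect_identical(a$extras$presso_global_p, b$extras$presso_global_p)
  expect_identical(a$beta, b$beta)
})

test_that("run_mr dispatches on instrument count", {
  mk <- function(m) harmonised_set(seq(0.2, 0.5, length.out = m),
                                   rep(0.01, m),
                                   0.2 * seq(0.2, 0.5, length.out = m),
                                   rep(0.04, m))
  r1 <- run_mr(mk(1))
  expect_equal(vapply(r1, `[[`, character(1), "method"), "ratio")
  r2 <- run_mr(mk(2))
  expect_equal(vapply(r2, `[[`, character(1), "method"), "ivw")
  r3 <- run_mr(mk(3), mr_config(seed = 1))
  expect_setequal(vapply(r3, `[[`, character(1), "method"),
                  c("ivw", "weighted_median", "egger"))
  r5 <- run_mr(mk(5), mr_config(seed = 1))
  expect_setequal(vapply(r5, `[[`, character(1), "method"),
                  c("ivw", "weighted_median", "egger", "presso"))
  expect_equal(r5[[1]]$role, "main")
  expect_true(all(vapply(r5[-1], `[[`, character(1), "role") ==
                    "sensitivity"))
})

test_that("odds-ratio conversion is exact exponentiation", {
  expect_equal(unname(or_from_beta(0, 0.1)["or"]), 1)
  expect_equal(unname(or_from_beta(log(2), 0)["or"]), 2)
  got <- or_from_beta(0.1222, 0.0316)
  expect_equal(unname(got["or"]), exp(0.1222), tolerance = 1e-12)
  expect_equal(round(unname(got["or"]), 2), 1.13)
  expect_equal(round(unname(got["ci_low"]), 2), 1.06)
  expect_equal(round(unname(got["ci_high"]), 2), 1.20)
})

test_that("all estimators are invariant to joint allele flips", {
  set.seed(49)
  m <- 6
  h <- harmonised_set(runif(m, 0.1, 0.5), runif(m, 0.005, 0.02),
                      rnorm(m, 0.1, 0.1), runif(m, 0.02, 0.08))
  h_flip <- h
  h_flip$beta_exp[c(2, 5)] <- -h_flip$beta_exp[c(2, 5)]
  h_flip$beta_out[c(2, 5)] <- -h_flip$beta_out[c(2, 5)]
  cfg <- mr_config(seed = 3)
  for (f in list(mr_ivw, mr_egger)) {
    expect_equal(f(h, cfg)$beta, f(h_flip, cfg)$beta, tolerance = 1e-12)
    expect_equal(f(h, cfg)$se, f(h_flip, cfg)$se, tolerance = 1e-12)
  }
  expect_equal(mr_weighted_median(h, cfg)$beta,
               mr_weighted_median(h_flip, cfg)$beta, tolerance = 1e-12)
  expect_equal(mr_presso(h, cfg)$beta, mr_presso(h_flip, cfg)$beta,
               tolerance = 1e-12)
})

test_that("estimates scale with the outcome: beta and se both multiply", {
  set.seed(50)
  m <- 5
  h <- harmonised_set(runif(m, 0.1, 0.5), runif(m, 0.005, 0.02),
                      rnorm(m, 0.1, 0.1), runif(m, 0.02, 0.08))
  c_scale <- 2.5
  h2 <- h
  h2$beta_out <- c_scale * h2$beta_out
  h2$se_out <- c_scale * h2$se_out
  cfg <- mr_config(seed = 4)
  for (f in list(mr_ivw, mr_egger, mr_weighted_median)) {
    a <- f(h, cfg); b <- f(h2, cfg)
    expect_equal(b$beta, c_scale * a$beta, tolerance = 1e-10)
    expect_equal(b$se, c_scale * a$se, tolerance = 1e-10)
  }
})

test_that("tidiers return one row per method with diagnostics", {
  h <- harmonised_set(seq(0.2, 0.5, length.out = 5), rep(0.01, 5),
                      0.2 * seq(0.2, 0.5, length.out = 5), rep(0.04, 5))
  res <- run_mr(h, mr_config(seed = 2))
  tbl <- tidy_mr_suite(res)
  expect_equal(nrow(tbl), 4)
  expect_true(all(c("estimate", "std.error", "p.value") %in% names(tbl)))
  g <- generics::glance(res[[1]])
  expect_true("Q" %in% names(g))
})
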