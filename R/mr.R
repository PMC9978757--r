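#' Configure the stochastic components of the MR estimators
#'
#' @param n_boot Parametric-bootstrap replicates for the weighted-median
#'   standard error (>= 100, default 1000).
#' @param n_sim Simulations for the MR-PRESSO global, outlier and
#'   distortion tests (>= 100, default 1000).
#' @param seed Integer seed; the bootstrap and all PRESSO simulations are
#'   reproducible given the seed.
#' @param presso_outlier_alpha Significance level for the outlier test,
#'   Bonferroni-corrected over the number of instruments (default 0.05).
#' @return A list of class `mr_config`.
#' @export
mr_config <- function(n_boot = 1000L, n_sim = 1000L, seed = 1L,
                      presso_outlier_alpha = 0.05) {
  stopifnot(n_boot >= 100, n_sim >= 100,
            presso_outlier_alpha > 0, presso_outlier_alpha < 1)
  structure(list(n_boot = as.integer(n_boot), n_sim = as.integer(n_sim),
                 seed = as.integer(seed),
                 presso_outlier_alpha = presso_outlier_alpha),
            class = "mr_config")
}

new_mr_result <- function(method, beta, se, n_snp, extras = list(),
                          role = "main") {
  structure(list(
    method = method, beta = beta, se = se,
    ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
    p = min(2 * pnorm(-abs(beta / se)), 1),
    n_snp = as.integer(n_snp), extras = extras, role = role
  ), class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf(
    "<MR %s> beta = %.4g (95%% CI %.4g to %.4g), se = %.4g, p = %.3g, %d SNP(s)\n",
    x$method, x$beta, x$ci_low, x$ci_high, x$se, x$p, x$n_snp))
  if (length(x$extras) > 0) {
    cat("  extras:", paste(names(x$extras),
                           vapply(x$extras, function(e)
                             paste(format(e, digits = 4), collapse = ","),
                             character(1)),
                           sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = beta_out / beta_exp`, with the first-order delta-method standard
#' error `se_out / |beta_exp|` (the exposure uncertainty is ignored, the
#' usual leading-order approximation).
#'
#' @param h A `cyto_harmonised` set with exactly one variant and non-zero
#'   exposure beta.
#' @return An `mr_result`.
#' @export
wald_ratio <- function(h) {
  if (nrow(h) != 1) stop("wald_ratio requires exactly 1 variant", call. = FALSE)
  if (h$beta_exp == 0) stop("exposure beta is zero", call. = FALSE)
  new_mr_result("ratio",
                beta = h$beta_out / h$beta_exp,
                se = h$se_out / abs(h$beta_exp),
                n_snp = 1L)
}

# IVW internals shared with PRESSO: weighted regression through the origin.
ivw_fit <- function(bx, by, sey) {
  w <- 1 / sey^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  q <- sum(w * (by - beta * bx)^2)
  list(beta = beta, se_fe = 1 / sqrt(sxx), q = q)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted least squares of outcome betas on exposure betas through the
#' origin with weights `1/se_out^2`. The fixed-effects standard error is
#' inflated multiplicatively by `sqrt(max(1, Q / (n_snp - 1)))`, where Q is
#' Cochran's heterogeneity statistic, so the estimator reduces to plain
#' fixed effects when heterogeneity is at or below its expectation.
#'
#' @param h A `cyto_harmonised` set with at least 2 variants.
#' @param config An [mr_config()] (unused by IVW itself; accepted for a
#'   uniform interface).
#' @return An `mr_result` with `Q` in `$extras`.
#' @export
mr_ivw <- function(h, config = mr_config()) {
  if (nrow(h) < 2) {
    stop("ivw requires >= 2 variants; use wald_ratio for a single instrument",
         call. = FALSE)
  }
  f <- ivw_fit(h$beta_exp, h$beta_out, h$se_out)
  infl <- sqrt(max(1, f$q / (nrow(h) - 1)))
  new_mr_result("ivw", beta = f$beta, se = f$se_fe * infl, n_snp = nrow(h),
                extras = list(Q = f$q))
}

# Weighted median of ratios r with weights w: sort, cumulative
# s_j = cumsum(w') - w'/2, linear interpolation at s = 0.5.
weighted_median_point <- function(r, w) {
  ord <- order(r)
  r <- r[ord]
  w <- w[ord] / sum(w)
  s <- cumsum(w) - w / 2
  hit <- which(abs(s - 0.5) < 1e-12)
  if (length(hit) > 0) return(r[hit[1]])
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(s)])
  below <- max(which(s < 0.5))
  r[below] + (r[below + 1] - r[below]) * (0.5 - s[below]) /
    (s[below + 1] - s[below])
}

#' Weighted-median MR estimate
#'
#' Consistent when instruments carrying at least half of the weight are
#' valid. Per-variant ratios `beta_out/beta_exp` receive weights
#' `beta_exp^2 / se_out^2` (the inverse variance of the ratio to first
#' order); the estimate interpolates the weighted empirical distribution of
#' ratios at probability 0.5. The standard error is the standard deviation
#' of the estimate over `config$n_boot` parametric-bootstrap replicates
#' drawing `beta_exp* ~ N(beta_exp, se_exp)` and
#' `beta_out* ~ N(beta_out, se_out)`.
#'
#' @param h A `cyto_harmonised` set with at least 3 variants and no zero
#'   exposure beta.
#' @param config An [mr_config()]; the bootstrap is seeded from it.
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(h, config = mr_config()) {
  if (nrow(h) < 3) stop("weighted_median requires >= 3 variants", call. = FALSE)
  if (any(h$beta_exp == 0)) stop("exposure beta of zero", call. = FALSE)
  ratio <- h$beta_out / h$beta_exp
  w <- h$beta_exp^2 / h$se_out^2
  est <- weighted_median_point(ratio, w)
  m <- nrow(h)
  boots <- withr::with_seed(config$seed, {
    bx <- matrix(rnorm(config$n_boot * m, mean = rep(h$beta_exp, each = config$n_boot),
                       sd = rep(h$se_exp, each = config$n_boot)),
                 nrow = config$n_boot)
    by <- matrix(rnorm(config$n_boot * m, mean = rep(h$beta_out, each = config$n_boot),
                       sd = rep(h$se_out, each = config$n_boot)),
                 nrow = config$n_boot)
    vapply(seq_len(config$n_boot), function(b) {
      rb <- by[b, ] / bx[b, ]
      wb <- bx[b, ]^2 / h$se_out^2
      weighted_median_point(rb, wb)
    }, numeric(1))
  })
  new_mr_result("weighted_median", beta = est, se = sd(boots), n_snp = m,
                role = "sensitivity")
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome betas on exposure betas with a free
#' intercept (weights `1/se_out^2`), after orienting every variant so its
#' exposure beta is positive. The slope is the causal estimate; the
#' intercept estimates average directional pleiotropy and its Wald test is
#' reported in `$extras`. Standard errors carry the multiplicative
#' dispersion factor `sqrt(max(1, RSS_w / (n_snp - 2)))`.
#'
#' @param h A `cyto_harmonised` set with at least 3 variants.
#' @param config An [mr_config()] (interface uniformity).
#' @return An `mr_result` with `egger_intercept`, `egger_intercept_se` and
#'   `egger_intercept_p` in `$extras`.
#' @export
mr_egger <- function(h, config = mr_config()) {
  if (nrow(h) < 3) stop("egger requires >= 3 variants", call. = FALSE)
  flip <- sign(h$beta_exp)
  flip[flip == 0] <- 1
  bx <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  x <- cbind(1, bx)
  xtw <- t(x * w)
  xtwx_inv <- solve(xtw %*% x)
  coef <- as.vector(xtwx_inv %*% (xtw %*% by))
  resid <- by - as.vector(x %*% coef)
  rss_w <- sum(w * resid^2)
  infl <- sqrt(max(1, rss_w / (nrow(h) - 2)))
  ses <- unname(sqrt(diag(xtwx_inv))) * infl
  res <- new_mr_result("egger", beta = coef[2], se = ses[2], n_snp = nrow(h),
                       role = "sensitivity",
                       extras = list(
                         egger_intercept = coef[1],
                         egger_intercept_se = ses[1],
                         egger_intercept_p =
                           min(2 * pnorm(-abs(coef[1] / ses[1])), 1),
                         rss_w = rss_w))
  res
}

# Leave-one-out IVW point estimates via sum updates (vectorised).
ivw_loo <- function(bx, by, w) {
  sxx <- sum(w * bx^2)
  sxy <- sum(w * bx * by)
  (sxy - w * bx * by) / (sxx - w * bx^2)
}

#' MR-PRESSO outlier-robust sensitivity analysis
#'
#' Simulation-based residual-sum-of-squares test for horizontal-pleiotropy
#' outliers. The observed statistic is
#' `RSS = sum_j w_j (beta_out_j - beta_loo_j * beta_exp_j)^2` with
#' leave-one-out IVW estimates `beta_loo_j` and weights `w_j = 1/se_out^2`.
#' `config$n_sim` parametric simulations (drawing
#' `beta_exp* ~ N(beta_exp, se_exp)` and
#' `beta_out_j* ~ N(beta_loo_j * beta_exp_j, se_out_j)`) give the null
#' distribution: the global p-value is the add-one empirical tail
#' probability, and each variant's contribution is compared with its own
#' simulated distribution for outlier flagging at
#' `presso_outlier_alpha / n_snp`. When outliers are flagged, the headline
#' estimate switches to the outlier-removed IVW and a distortion p-value
#' compares the full and outlier-removed estimates against the distortion
#' expected from removing random subsets of the same size.
#'
#' @param h A `cyto_harmonised` set with at least 4 variants.
#' @param config An [mr_config()].
#' @return An `mr_result` with `presso_global_p`, `presso_outliers`
#'   (variant ids), `presso_rss` and, when outliers are found,
#'   `presso_distortion_p` and `beta_raw` (the all-instrument IVW beta) in
#'   `$extras`.
#' @export
mr_presso <- function(h, config = mr_config()) {
  m <- nrow(h)
  if (m < 4) stop("presso requires >= 4 variants", call. = FALSE)
  bx <- h$beta_exp; by <- h$beta_out
  sex <- h$se_exp; sey <- h$se_out
  w <- 1 / sey^2

  beta_loo <- ivw_loo(bx, by, w)
  resid_obs <- w * (by - beta_loo * bx)^2
  rss_obs <- sum(resid_obs)

  sim <- withr::with_seed(config$seed, {
    ns <- config$n_sim
    bx_s <- matrix(rnorm(ns * m, rep(bx, each = ns), rep(sex, each = ns)),
                   nrow = ns)
    by_s <- matrix(rnorm(ns * m, rep(beta_loo * bx, each = ns),
                         rep(sey, each = ns)), nrow = ns)
    # recompute LOO-based residuals on each simulated data set
    wm <- matrix(w, nrow = ns, ncol = m, byrow = TRUE)
    sxx_s <- rowSums(wm * bx_s^2)
    sxy_s <- rowSums(wm * bx_s * by_s)
    bloo_s <- (sxy_s - wm * bx_s * by_s) / (sxx_s - wm * bx_s^2)
    res_s <- wm * (by_s - bloo_s * bx_s)^2
    list(rss = rowSums(res_s), res = res_s)
  })
  global_p <- (1 + sum(sim$rss >= rss_obs)) / (config$n_sim + 1)

  # per-variant outlier p from each variant's simulated residual distribution
  outlier_p <- vapply(seq_len(m), function(j) {
    (1 + sum(sim$res[, j] >= resid_obs[j])) / (config$n_sim + 1)
  }, numeric(1))
  is_outlier <- outlier_p < config$presso_outlier_alpha / m

  ivw_all <- mr_ivw(h, config)
  extras <- list(presso_global_p = global_p,
                 presso_outliers = h$variant_id[is_outlier],
                 presso_outlier_p = outlier_p,
                 presso_rss = rss_obs)

  if (any(is_outlier) && sum(!is_outlier) >= 2) {
    keep <- !is_outlier
    ivw_kept <- mr_ivw(h[keep, ], config)
    d_obs <- ivw_all$beta - ivw_kept$beta
    n_out <- sum(is_outlier)
    d_sim <- withr::with_seed(config$seed + 1L, {
      vapply(seq_len(config$n_sim), function(s) {
        drop_idx <- sample.int(m, n_out)
        f <- ivw_fit(bx[-drop_idx], by[-drop_idx], sey[-drop_idx])
        ivw_all$beta - f$beta
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (config$n_sim + 1)
    extras$presso_distortion_p <- distortion_p
    extras$beta_raw <- ivw_all$beta
    res <- new_mr_result("presso", beta = ivw_kept$beta, se = ivw_kept$se,
                         n_snp = as.integer(sum(keep)), extras = extras,
                         role = "sensitivity")
  } else {
    res <- new_mr_result("presso", beta = ivw_all$beta, se = ivw_all$se,
                         n_snp = m, extras = extras, role = "sensitivity")
  }
  res
}

#' Run the full MR estimator suite with the dispatch rule
#'
#' One instrument: the Wald ratio is the main analysis. Two or more: IVW is
#' the main analysis. Three or more instruments additionally trigger the
#' weighted-median and MR-Egger sensitivity analyses, and four or more
#' MR-PRESSO.
#'
#' @param h A `cyto_harmonised` set.
#' @param config An [mr_config()].
#' @return A list of `mr_result` objects; the first carries
#'   `role = "main"`.
#' @export
run_mr <- function(h, config = mr_config()) {
  m <- nrow(h)
  if (m < 1) stop("empty harmonised set", call. = FALSE)
  if (m == 1) return(list(wald_ratio(h)))
  out <- list(mr_ivw(h, config))
  if (m >= 3) {
    out <- c(out, list(mr_weighted_median(h, config), mr_egger(h, config)))
  }
  if (m >= 4) {
    out <- c(out, list(mr_presso(h, config)))
  }
  out
}

#' Odds ratio (with 95% CI) from a log-odds beta
#'
#' For binary outcomes the MR estimate is on the log-odds scale per 1
#' standard deviation of the exposure; this converts it to an odds ratio.
#'
#' @param beta Log-odds effect.
#' @param se Its standard error (> 0, or 0 for a point value).
#' @return Named vector `or`, `ci_low`, `ci_high`.
#' @export
or_from_beta <- function(beta, se) {
  stopifnot(se >= 0)
  c(or = exp(beta), ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se))
}
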