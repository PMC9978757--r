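#' Colocalisation priors and effect-variance hyperparameters
#'
#' @param p1,p2 Prior probability that a variant is causal for trait 1 /
#'   trait 2 (default 1e-4 each).
#' @param p12 Prior probability that a variant is causal for both traits
#'   (default 1e-5); must satisfy `0 < p12 <= min(p1, p2)` and
#'   `p1 + p2 + p12 < 1`.
#' @param w1,w2 Prior variance of the causal effect for each trait.
#'   Defaults follow the usual convention: `0.2^2` for quantitative traits
#'   and `0.15^2` on the log-odds scale for binary traits (see
#'   `coloc_prior_variance()`).
#' @return A list of class `coloc_config`.
#' @export
coloc_config <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                         w1 = 0.2^2, w2 = 0.2^2) {
  stopifnot(p12 > 0, p12 <= min(p1, p2), p1 + p2 + p12 < 1, w1 > 0, w2 > 0)
  structure(list(p1 = p1, p2 = p2, p12 = p12, w1 = w1, w2 = w2),
            class = "coloc_config")
}

#' @rdname coloc_config
#' @param trait_type Trait type string as in [sumstats()].
#' @return `coloc_prior_variance()` returns the conventional prior effect
#'   variance for a trait type.
#' @export
coloc_prior_variance <- function(trait_type) {
  if (identical(trait_type, "binary")) 0.15^2 else 0.2^2
}

#' Wakefield's log approximate Bayes factor for one association
#'
#' With `z = beta/se` and shrinkage `r = w / (w + se^2)`,
#' `log ABF = 0.5 * (log(1 - r) + r * z^2)`: the evidence for a real effect
#' against the point null under a normal prior with variance `w`.
#'
#' @param beta,se Association estimate and standard error (`se > 0`).
#' @param w Prior effect variance (> 0).
#' @return Log approximate Bayes factor (vectorised).
#' @export
wakefield_labf <- function(beta, se, w) {
  stopifnot(all(se > 0), all(w > 0))
  z <- beta / se
  r <- w / (w + se^2)
  0.5 * (log1p(-r) + r * z^2)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b, -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Approximate-Bayes-factor colocalisation of two traits at a locus
#'
#' Enumerates, over the locus's shared variants, the five hypotheses: no
#' association with either trait (H0), association with trait 1 only (H1),
#' trait 2 only (H2), both traits via distinct causal variants (H3), and
#' both traits via a single shared causal variant (H4). Per-variant
#' Wakefield log Bayes factors are combined with the configured priors in
#' log space; the posterior is their softmax. `pp_shared` aliases PP(H4)
#' and `pp_distinct` PP(H3).
#'
#' The decision flags implement the support rule
#' `PP_shared + PP_distinct > 0.5` and the ratio rule
#' `PP_shared / (PP_shared + PP_distinct) > 0.5`; both passing is taken as
#' evidence for colocalising signals, while a high `pp_distinct` suggests
#' genetic confounding by a nearby but different causal variant.
#'
#' @param trait1,trait2 Tibbles of association records (`variant_id`,
#'   `beta`, `se`) for the same locus; they are intersected on
#'   `variant_id`, and effects are assumed already aligned to a common
#'   effect allele (use [harmonise()] upstream).
#' @param config A [coloc_config()].
#' @return A list of class `coloc_result` with elements `pp` (named vector
#'   PP_H0..PP_H4), `pp_shared`, `pp_distinct`, `n_variants`,
#'   `passes_support`, `passes_ratio` and `degenerate` (TRUE when fewer
#'   than 2 shared variants make H3 impossible).
#' @export
colocalise <- function(trait1, trait2, config = coloc_config()) {
  t1 <- tibble::as_tibble(trait1)
  t2 <- tibble::as_tibble(trait2)
  shared <- intersect(t1$variant_id, t2$variant_id)
  if (length(shared) == 0) stop("no shared variants at locus", call. = FALSE)
  t1 <- t1[match(shared, t1$variant_id), ]
  t2 <- t2[match(shared, t2$variant_id), ]
  ok <- is.finite(t1$se) & is.finite(t2$se) & t1$se > 0 & t2$se > 0
  t1 <- t1[ok, ]; t2 <- t2[ok, ]
  nv <- nrow(t1)
  if (nv == 0) stop("no usable shared variants at locus", call. = FALSE)
  degenerate <- nv < 2
  if (degenerate) {
    warning("fewer than 2 shared variants: H3 is combinatorially impossible",
            call. = FALSE)
  }

  l1 <- wakefield_labf(t1$beta, t1$se, config$w1)
  l2 <- wakefield_labf(t2$beta, t2$se, config$w2)

  s1 <- logsumexp(l1)
  s2 <- logsumexp(l2)
  s12 <- logsumexp(l1 + l2)
  L <- c(
    H0 = 0,
    H1 = log(config$p1) + s1,
    H2 = log(config$p2) + s2,
    H3 = log(config$p1) + log(config$p2) + logdiffexp(s1 + s2, s12),
    H4 = log(config$p12) + s12
  )
  mx <- max(L)
  pp <- exp(L - mx) / sum(exp(L - mx))
  names(pp) <- paste0("PP_", names(L))
  pp_shared <- unname(pp["PP_H4"])
  pp_distinct <- unname(pp["PP_H3"])
  structure(list(
    pp = pp, pp_shared = pp_shared, pp_distinct = pp_distinct,
    n_variants = nv,
    passes_support = (pp_shared + pp_distinct) > 0.5,
    passes_ratio = (pp_shared + pp_distinct) > 0 &&
      pp_shared / (pp_shared + pp_distinct) > 0.5,
    degenerate = degenerate, config = config
  ), class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat("<colocalisation> ", x$n_variants, " variants\n", sep = "")
  print(round(x$pp, 4))
  cat("support rule (PP_shared + PP_distinct > 0.5): ",
      x$passes_support, "\n", sep = "")
  cat("ratio rule (PP_shared / (PP_shared + PP_distinct) > 0.5): ",
      x$passes_ratio, "\n", sep = "")
  invisible(x)
}
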