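# Small in-code fixtures shared across test files.

# A well-formed summary-statistics tibble (betas/ses arbitrary but valid).
toy_sumstats <- function(trait_id = "trait", n_var = 5, trait_type = "quantitative",
                         ea = NULL, oa = NULL, beta = NULL, p = NULL,
                         pos = NULL, eaf = NULL) {
  m <- n_var
  tbl <- tibble::tibble(
    variant_id = paste0("rs", seq_len(m)),
    chrom = "1",
    pos = pos %||% (seq_len(m) * 1000L),
    ea = ea %||% rep("A", m),
    oa = oa %||% rep("G", m),
    eaf = eaf %||% rep(0.3, m),
    beta = beta %||% seq(0.1, 0.5, length.out = m),
    se = rep(0.05, m),
    p = p %||% rep(1e-5, m),
    n = rep(1000L, m)
  )
  sumstats(tbl, trait_id = trait_id, trait_type = trait_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Identity LD matrix over the toy variant ids.
toy_ld <- function(ids) {
  r <- diag(length(ids))
  dimnames(r) <- list(ids, ids)
  r
}

# Independent greedy-clumping oracle: straight transcription of the rule,
# kept free of the package's implementation.
oracle_clump <- function(tbl, ld, r2_max, p_max) {
  tbl <- tbl[tbl$p < p_max, ]
  tbl <- tbl[order(tbl$p, tbl$pos, paste(tbl$ea, tbl$oa)), ]
  kept <- character(0)
  for (i in seq_len(nrow(tbl))) {
    v <- tbl$variant_id[i]
    if (all(ld[v, kept]^2 < r2_max)) kept <- c(kept, v)
  }
  tbl[match(kept, tbl$variant_id), ]
}

# Independent weighted-median oracle using stats::approx on the weighted
# empirical CDF.
oracle_weighted_median <- function(r, w) {
  o <- order(r)
  r <- r[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (any(abs(s - 0.5) < 1e-12)) return(r[which(abs(s - 0.5) < 1e-12)[1]])
  stats::approx(s, r, xout = 0.5)$y
}

# Exhaustive enumeration oracle for colocalisation posteriors on a tiny
# locus: sums the un-normalised posterior mass of every causal
# configuration directly (safe without log-space at test scale).
oracle_coloc <- function(b1, s1, b2, s2, p1, p2, p12, w1, w2) {
  abf1 <- exp(cytomr::wakefield_labf(b1, s1, w1))
  abf2 <- exp(cytomr::wakefield_labf(b2, s2, w2))
  m <- length(b1)
  h0 <- 1
  h1 <- p1 * sum(abf1)
  h2 <- p2 * sum(abf2)
  h3 <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    if (i != j) h3 <- h3 + p1 * p2 * abf1[i] * abf2[j]
  }
  h4 <- p12 * sum(abf1 * abf2)
  tot <- h0 + h1 + h2 + h3 + h4
  c(PP_H0 = h0, PP_H1 = h1, PP_H2 = h2, PP_H3 = h3, PP_H4 = h4) / tot
}
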