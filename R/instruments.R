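#' Greedy LD clumping of association records
#'
#' Keeps candidates with `p < p_max`, sorts them by ascending p-value (ties
#' broken by position, then by allele strings, for determinism), accepts in
#' order and discards any later candidate whose squared correlation with an
#' already accepted variant is at least `r2_max`. The output is therefore a
#' set of sub-threshold variants that are pairwise approximately independent
#' in the LD reference.
#'
#' @param records A `cyto_sumstats` tibble (or any tibble with
#'   `variant_id`, `pos`, `ea`, `oa`, `p` columns).
#' @param ld Square LD correlation matrix `r` with variant row names
#'   covering all candidates.
#' @param r2_max Pairwise r-squared ceiling in (0, 1); the retained set has
#'   all pairwise r-squared strictly below it.
#' @param p_max P-value threshold (strict: `p < p_max`).
#' @return The retained rows, in acceptance (ascending p) order.
#' @export
clump <- function(records, ld, r2_max = 0.001, p_max = 5e-8) {
  stopifnot(r2_max > 0, r2_max < 1)
  cand <- tibble::as_tibble(records)
  cand <- cand[cand$p < p_max, ]
  if (nrow(cand) == 0) return(records[0, ])
  missing_ld <- setdiff(cand$variant_id, rownames(ld))
  if (length(missing_ld) > 0) {
    stop("variant(s) missing from LD reference: ",
         paste(utils::head(missing_ld, 5), collapse = ", "), call. = FALSE)
  }
  ord <- order(cand$p, cand$pos, paste(cand$ea, cand$oa))
  cand <- cand[ord, ]
  accepted <- integer(0)
  for (i in seq_len(nrow(cand))) {
    vi <- cand$variant_id[i]
    if (length(accepted) == 0) {
      accepted <- i
      next
    }
    r2 <- ld[vi, cand$variant_id[accepted]]^2
    if (all(r2 < r2_max)) accepted <- c(accepted, i)
  }
  cand[accepted, ]
}

new_instrument_set <- function(rows, exposure_id, criterion, locus = NULL) {
  tbl <- tibble::as_tibble(rows)[, c("variant_id", "chrom", "pos", "ea",
                                     "oa", "eaf", "beta", "se", "p", "n")]
  structure(tbl,
            class = c("cyto_instruments", class(tibble::tibble())),
            exposure_id = exposure_id, criterion = criterion, locus = locus)
}

#' @export
print.cyto_instruments <- function(x, ...) {
  cat("<instrument set> exposure: ", attr(x, "exposure_id"),
      ", criterion: ", attr(x, "criterion"), ", ", nrow(x),
      " variant(s)\n", sep = "")
  NextMethod()
}

#' Instrument-set metadata accessors
#'
#' @param x A `cyto_instruments` tibble.
#' @return The selection criterion label / the exposure id.
#' @export
criterion <- function(x) attr(x, "criterion")

#' @rdname criterion
#' @export
exposure_id <- function(x) attr(x, "exposure_id")

#' Select genome-wide instruments for a cardiometabolic trait
#'
#' Variants associated with the trait at `p < p_max` (default 5e-8; the
#' fasting-insulin convention is 1e-6) and pairwise uncorrelated at
#' `r2 < r2_max`.
#'
#' @param trait A `cyto_sumstats` tibble.
#' @param ld LD correlation matrix.
#' @param p_max Significance threshold.
#' @param r2_max Clumping ceiling (default 0.001).
#' @return A `cyto_instruments` tibble (possibly empty, with a warning).
#' @export
select_trait_instruments <- function(trait, ld, p_max = 5e-8,
                                     r2_max = 0.001) {
  kept <- clump(trait, ld, r2_max = r2_max, p_max = p_max)
  if (nrow(kept) == 0) {
    warning("no instruments for ", trait_id(trait), " at p < ", p_max,
            call. = FALSE)
  }
  new_instrument_set(kept, exposure_id = trait_id(trait),
                     criterion = "trait_gwas")
}

in_cis_window <- function(tbl, locus, window) {
  tbl$chrom == locus$chrom &
    tbl$pos >= locus$start - window &
    tbl$pos <= locus$end + window
}

#' Select cis-pQTL instruments for a cytokine
#'
#' Variants within `window` base pairs (inclusive) of the cytokine's gene
#' locus that associate with the circulating cytokine level at
#' `p < p_max`, clumped to pairwise `r2 < r2_max`.
#'
#' @param cytokine Cytokine `cyto_sumstats`.
#' @param locus One-row gene-locus tibble (see [gene_locus()]).
#' @param ld LD correlation matrix.
#' @param window Flank size in base pairs (default 500 kb).
#' @param p_max Cytokine association threshold (default 1e-4).
#' @param r2_max Clumping ceiling.
#' @return A `cyto_instruments` tibble with `criterion = "cis_pqtl"`.
#' @export
select_cis_pqtl <- function(cytokine, locus, ld, window = 500000L,
                            p_max = 1e-4, r2_max = 0.001) {
  tbl <- tibble::as_tibble(cytokine)
  tbl <- tbl[in_cis_window(tbl, locus, window), ]
  kept <- clump(tbl, ld, r2_max = r2_max, p_max = p_max)
  new_instrument_set(kept, exposure_id = trait_id(cytokine),
                     criterion = "cis_pqtl", locus = locus)
}

#' Select cis-eQTL instruments for a cytokine
#'
#' Variants within the gene window associated with both the gene's
#' expression aggregated across tissues (`p < p_expr_max`) and the
#' circulating cytokine level (`p < p_cyt_max`). Exposure effects are taken
#' from the cytokine summary statistics, so downstream MR estimates are on
#' the circulating-protein scale.
#'
#' @param cytokine Cytokine `cyto_sumstats` (supplies the exposure betas).
#' @param agg_expression Cross-tissue aggregated expression
#'   `cyto_sumstats` for the cytokine's gene (see [aggregate_tissues()]).
#' @param locus,ld,window,r2_max As in [select_cis_pqtl()].
#' @param p_expr_max Expression threshold (default 1e-4).
#' @param p_cyt_max Cytokine threshold (default 0.05).
#' @return A `cyto_instruments` tibble with `criterion = "cis_eqtl"`.
#' @export
select_cis_eqtl <- function(cytokine, agg_expression, locus, ld,
                            window = 500000L, p_expr_max = 1e-4,
                            p_cyt_max = 0.05, r2_max = 0.001) {
  tbl <- tibble::as_tibble(cytokine)
  tbl <- tbl[in_cis_window(tbl, locus, window), ]
  etbl <- tibble::as_tibble(agg_expression)
  idx <- match(paste(tbl$chrom, tbl$pos), paste(etbl$chrom, etbl$pos))
  p_expr <- etbl$p[idx]
  tbl <- tbl[!is.na(p_expr) & p_expr < p_expr_max & tbl$p < p_cyt_max, ]
  # clump ranks by the cytokine p-value (the exposure scale)
  kept <- clump(tbl, ld, r2_max = r2_max, p_max = p_cyt_max)
  new_instrument_set(kept, exposure_id = trait_id(cytokine),
                     criterion = "cis_eqtl", locus = locus)
}

#' Select genome-wide instruments for a cytokine (secondary criterion)
#'
#' Uncorrelated (`r2 < r2_max`) variants from across the genome associated
#' with the cytokine concentration at `p < 5e-8`; unlike the cis criteria
#' this admits trans signals.
#'
#' @param cytokine Cytokine `cyto_sumstats`.
#' @param ld LD correlation matrix.
#' @param p_max Threshold (default 5e-8).
#' @param r2_max Clumping ceiling.
#' @return A `cyto_instruments` tibble with
#'   `criterion = "genomewide_cytokine"`.
#' @export
select_genomewide_cytokine <- function(cytokine, ld, p_max = 5e-8,
                                       r2_max = 0.001) {
  kept <- clump(cytokine, ld, r2_max = r2_max, p_max = p_max)
  new_instrument_set(kept, exposure_id = trait_id(cytokine),
                     criterion = "genomewide_cytokine")
}

#' Harmonise an instrument set against outcome summary statistics
#'
#' Restricts the outcome to the instruments' variants and aligns effect
#' alleles, producing the input to [run_mr()].
#'
#' @param instruments A `cyto_instruments` tibble.
#' @param outcome Outcome `cyto_sumstats`.
#' @param ... Passed to [harmonise()].
#' @return A `cyto_harmonised` tibble.
#' @export
harmonise_instruments <- function(instruments, outcome, ...) {
  exp_ss <- sumstats(tibble::as_tibble(instruments),
                     trait_id = attr(instruments, "exposure_id"))
  harmonise(exp_ss, outcome, ...)
}
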