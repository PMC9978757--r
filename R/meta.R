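#' Inverse-variance-weighted fixed-effects meta-analysis
#'
#' Pools per-cohort GWAS associations. Each study after the first is allele
#' aligned to the first study via [harmonise()]; per variant with weights
#' `w_i = 1/se_i^2`, `beta_meta = sum(w_i * beta_i) / sum(w_i)` and
#' `se_meta = 1 / sqrt(sum(w_i))`, with a two-sided normal p-value. Variants
#' present in any study are emitted, pooled over the studies that carry
#' them; variants whose alleles cannot be reconciled with the first study
#' are dropped and counted in the attached report.
#'
#' @param studies List of `cyto_sumstats` tibbles for the same trait.
#' @param trait_id Identifier for the pooled trait (defaults to the first
#'   study's).
#' @param palindrome_eaf_limit Passed to [harmonise()].
#' @return A `cyto_sumstats` tibble with extra columns `k_studies`
#'   (contributing cohorts per variant); `n` is the summed sample size and
#'   `eaf` the sample-size-weighted mean frequency.
#' @export
meta_fixed <- function(studies, trait_id = NULL,
                       palindrome_eaf_limit = 0.42) {
  stopifnot(length(studies) >= 1)
  ref <- studies[[1]]
  trait_id <- trait_id %||% attr(ref, "trait_id")
  dropped <- 0L

  aligned <- vector("list", length(studies))
  aligned[[1]] <- tibble::as_tibble(ref)[, c("variant_id", "chrom", "pos",
                                             "ea", "oa", "eaf", "beta",
                                             "se", "p", "n")]
  if (length(studies) > 1) {
    for (i in seq_along(studies)[-1]) {
      h <- harmonise(ref, studies[[i]],
                     palindrome_eaf_limit = palindrome_eaf_limit)
      rep_i <- attr(h, "report")
      dropped <- dropped + sum(rep_i[c("irreconcilable",
                                       "palindromic_ambiguous")])
      shared <- sumstats_from_harmonised(h, "outcome")
      # variants unique to study i keep their own orientation
      only_i <- dplyr::anti_join(tibble::as_tibble(studies[[i]]),
                                 tibble::as_tibble(ref),
                                 by = c("chrom", "pos"))
      aligned[[i]] <- dplyr::bind_rows(
        tibble::as_tibble(shared)[, names(aligned[[1]])],
        only_i[, names(aligned[[1]])]
      )
    }
  }

  all_rows <- dplyr::bind_rows(aligned, .id = "study")
  pooled <- all_rows |>
    dplyr::mutate(w = 1 / .data$se^2) |>
    dplyr::group_by(.data$chrom, .data$pos) |>
    dplyr::summarise(
      variant_id = dplyr::first(.data$variant_id),
      ea = dplyr::first(.data$ea), oa = dplyr::first(.data$oa),
      eaf = sum(.data$eaf * .data$n) / sum(.data$n),
      beta = sum(.data$w * .data$beta) / sum(.data$w),
      se = 1 / sqrt(sum(.data$w)),
      n = sum(.data$n),
      k_studies = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(p = pmin(2 * pnorm(-abs(.data$beta / .data$se)), 1)) |>
    dplyr::arrange(.data$chrom, .data$pos)

  out <- sumstats(pooled[, c("variant_id", "chrom", "pos", "ea", "oa",
                             "eaf", "beta", "se", "p", "n")],
                  trait_id = trait_id,
                  trait_type = attr(ref, "trait_type"),
                  tissue = attr(ref, "tissue"),
                  report = c(irreconcilable = dropped))
  out$k_studies <- pooled$k_studies
  out
}

#' Aggregate per-tissue eQTL associations for a gene
#'
#' Pools expression associations across tissues with the same fixed-effects
#' machinery as the cohort meta-analysis (or, alternatively, an unweighted
#' Stouffer combination of z-scores). The per-variant cross-tissue z-score
#' is returned alongside; when a whole-blood tissue is present its
#' single-tissue z is also reported, supporting comparison of cross-tissue
#' and blood expression signals.
#'
#' @param eqtls List of `cyto_sumstats` objects with
#'   `trait_type = "expression"`, one per tissue, `trait_id` = gene.
#' @param gene Gene to aggregate; must be carried by at least one tissue.
#' @param method `"ivw"` (default, fixed-effects pooling of betas) or
#'   `"stouffer"` (equal-weight z combination; betas are then pooled IVW
#'   but `p` comes from the Stouffer z).
#' @param blood_label Regular expression identifying the whole-blood tissue.
#' @return A `cyto_sumstats` tibble with extra columns `z_cross_tissue`
#'   and, when a blood tissue is present, `z_blood`.
#' @export
aggregate_tissues <- function(eqtls, gene, method = c("ivw", "stouffer"),
                              blood_label = "blood") {
  method <- match.arg(method)
  mine <- Filter(function(s) attr(s, "trait_id") == gene, eqtls)
  if (length(mine) == 0) {
    stop("gene ", gene, " absent from all tissues", call. = FALSE)
  }
  agg <- meta_fixed(mine, trait_id = gene)
  agg$z_cross_tissue <- agg$beta / agg$se
  if (method == "stouffer") {
    zs <- lapply(mine, function(s) {
      tibble::tibble(chrom = s$chrom, pos = s$pos, z = s$beta / s$se)
    })
    zt <- dplyr::bind_rows(zs) |>
      dplyr::group_by(.data$chrom, .data$pos) |>
      dplyr::summarise(z = sum(.data$z) / sqrt(dplyr::n()), .groups = "drop")
    idx <- match(paste(agg$chrom, agg$pos), paste(zt$chrom, zt$pos))
    agg$z_cross_tissue <- zt$z[idx]
    agg$p <- pmin(2 * pnorm(-abs(agg$z_cross_tissue)), 1)
  }
  blood <- Filter(function(s) grepl(blood_label, attr(s, "tissue"),
                                    ignore.case = TRUE), mine)
  if (length(blood) > 0) {
    b <- blood[[1]]
    idx <- match(paste(agg$chrom, agg$pos), paste(b$chrom, b$pos))
    agg$z_blood <- (b$beta / b$se)[idx]
  }
  agg
}
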