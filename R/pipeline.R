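#' Bonferroni-corrected family threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param n_outcomes Number of outcomes tested in the family (>= 1).
#' @return `alpha / n_outcomes`. With the conventional alpha = 0.05 this
#'   gives 0.05/47 = 0.0011 for a 47-cytokine outcome family and
#'   0.05/15 = 0.0033 for 15 cardiometabolic outcomes.
#' @export
bonferroni_threshold <- function(alpha, n_outcomes) {
  stopifnot(alpha > 0, alpha < 1, n_outcomes >= 1)
  alpha / n_outcomes
}

#' Pipeline configuration
#'
#' Bundles the tuning parameters shared by the three analysis directions.
#'
#' @param alpha Family-wise error rate before Bonferroni correction.
#' @param mr An [mr_config()].
#' @param coloc_priors A [coloc_config()]; its effect variances are
#'   overridden per trait type via [coloc_prior_variance()].
#' @param cis_window Cis window flank in base pairs.
#' @param p_trait,p_cis_pqtl,p_cis_eqtl_expr,p_cis_eqtl_cyt,p_genomewide
#'   Selection thresholds for the respective criteria.
#' @param trait_p_overrides Named numeric vector of per-trait instrument
#'   thresholds overriding `p_trait` (the fasting-insulin convention is
#'   `c(fasting_insulin = 1e-6)`).
#' @param r2_max Clumping ceiling.
#' @param palindrome_eaf_limit Passed to [harmonise()].
#' @param coloc_nominal_p Run colocalisation in direction 3 for pairs with
#'   main MR `p` below this nominal level (default 0.05).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(alpha = 0.05, mr = mr_config(),
                            coloc_priors = coloc_config(),
                            cis_window = 500000L,
                            p_trait = 5e-8, p_cis_pqtl = 1e-4,
                            p_cis_eqtl_expr = 1e-4, p_cis_eqtl_cyt = 0.05,
                            p_genomewide = 5e-8,
                            trait_p_overrides = c(fasting_insulin = 1e-6),
                            r2_max = 0.001, palindrome_eaf_limit = 0.42,
                            coloc_nominal_p = 0.05) {
  structure(list(alpha = alpha, mr = mr, coloc_priors = coloc_priors,
                 cis_window = as.integer(cis_window), p_trait = p_trait,
                 p_cis_pqtl = p_cis_pqtl,
                 p_cis_eqtl_expr = p_cis_eqtl_expr,
                 p_cis_eqtl_cyt = p_cis_eqtl_cyt,
                 p_genomewide = p_genomewide,
                 trait_p_overrides = trait_p_overrides,
                 r2_max = r2_max,
                 palindrome_eaf_limit = palindrome_eaf_limit,
                 coloc_nominal_p = coloc_nominal_p),
            class = "pipeline_config")
}

# One analysed exposure-outcome pair -> a result row. The main result's
# beta/se/p drive the significance flag and the z score.
result_row <- function(exposure, outcome, criterion, results, threshold,
                       coloc = NULL, outcome_binary = FALSE) {
  main <- results[[1]]
  sens <- if (length(results) > 1) results[-1] else list()
  supported <- !is.null(coloc) && isTRUE(coloc$passes_support) &&
    isTRUE(coloc$passes_ratio)
  row <- tibble::tibble(
    exposure = exposure, outcome = outcome, criterion = criterion,
    method = main$method, n_snp = main$n_snp,
    beta = main$beta, se = main$se,
    ci_low = main$ci_low, ci_high = main$ci_high, p = main$p,
    z = main$beta / main$se,
    significant = main$p < threshold,
    sensitivity = list(sens),
    coloc = list(coloc),
    coloc_supported = supported
  )
  if (outcome_binary) {
    or <- or_from_beta(main$beta, main$se)
    row$or <- or[["or"]]
    row$or_ci_low <- or[["ci_low"]]
    row$or_ci_high <- or[["ci_high"]]
  }
  row
}

mr_for_instruments <- function(instr, outcome, config) {
  if (nrow(instr) == 0) return(NULL)
  h <- tryCatch(
    harmonise_instruments(instr, outcome,
                          palindrome_eaf_limit = config$palindrome_eaf_limit),
    error = function(e) NULL)
  if (is.null(h) || nrow(h) == 0) return(NULL)
  h <- h[h$beta_exp != 0, ]
  if (nrow(h) == 0) return(NULL)
  run_mr(h, config$mr)
}

#' Direction 1: cardiometabolic risk factors on cytokine concentrations
#'
#' For each risk trait, selects genome-wide instruments, harmonises them
#' against every cytokine's summary statistics and runs the MR suite. The
#' significance family is Bonferroni-corrected for the number of cytokine
#' outcomes. Traits without instruments are skipped (logged in the `skipped`
#' attribute), never fatal.
#'
#' @param risk_traits,cytokines Lists of `cyto_sumstats`.
#' @param ld LD correlation matrix covering the candidate instruments.
#' @param config A [pipeline_config()].
#' @return Tibble of result rows (one per analysed pair) with the family
#'   threshold in the `threshold` attribute.
#' @export
run_direction_1 <- function(risk_traits, cytokines, ld,
                            config = pipeline_config()) {
  threshold <- bonferroni_threshold(config$alpha, length(cytokines))
  skipped <- character(0)
  rows <- list()
  for (rt in risk_traits) {
    p_max <- config$trait_p_overrides[trait_id(rt)]
    if (is.na(p_max)) p_max <- config$p_trait
    instr <- suppressWarnings(
      select_trait_instruments(rt, ld, p_max = p_max,
                               r2_max = config$r2_max))
    if (nrow(instr) == 0) {
      skipped <- c(skipped, paste0(trait_id(rt), ": no instruments"))
      next
    }
    for (cy in cytokines) {
      res <- mr_for_instruments(instr, cy, config)
      if (is.null(res)) {
        skipped <- c(skipped,
                     paste0(trait_id(rt), "->", trait_id(cy),
                            ": no harmonisable instruments"))
        next
      }
      rows[[length(rows) + 1]] <-
        result_row(trait_id(rt), trait_id(cy), "trait_gwas", res, threshold)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold") <- threshold
  attr(out, "skipped") <- skipped
  out
}

# locus-window records of a trait around a gene, as a plain tibble
locus_records <- function(ss, locus, window) {
  tbl <- tibble::as_tibble(ss)
  tbl[in_cis_window(tbl, locus, window), ]
}

# colocalise exposure and outcome at the exposure gene locus, aligning the
# outcome's alleles to the exposure first
coloc_at_locus <- function(exposure_ss, outcome_ss, locus, config,
                           outcome_binary = FALSE) {
  h <- tryCatch(
    harmonise(exposure_ss, outcome_ss,
              palindrome_eaf_limit = config$palindrome_eaf_limit),
    error = function(e) NULL)
  if (is.null(h)) return(NULL)
  reg <- h[in_cis_window(h, locus, config$cis_window), ]
  if (nrow(reg) == 0) return(NULL)
  pri <- config$coloc_priors
  cc <- coloc_config(p1 = pri$p1, p2 = pri$p2, p12 = pri$p12,
                     w1 = coloc_prior_variance("quantitative"),
                     w2 = coloc_prior_variance(
                       if (outcome_binary) "binary" else "quantitative"))
  t1 <- tibble::tibble(variant_id = reg$variant_id, beta = reg$beta_exp,
                       se = reg$se_exp)
  t2 <- tibble::tibble(variant_id = reg$variant_id, beta = reg$beta_out,
                       se = reg$se_out)
  suppressWarnings(colocalise(t1, t2, cc))
}

#' Direction 2: cytokine-on-cytokine effects and the causal network
#'
#' For each exposure cytokine and each cis criterion (cis-pQTL and, where
#' aggregated expression is available, cis-eQTL), runs MR against every
#' other cytokine. Significant pairs (family threshold: alpha / number of
#' cytokines) are colocalised at the exposure gene locus, and the
#' significant edges form a directed cytokine graph whose undirected
#' projection (|beta| edge weights) is partitioned by greedy modularity
#' maximisation.
#'
#' @param cytokines List of `cyto_sumstats` (one per cytokine).
#' @param ld LD correlation matrix.
#' @param loci Tibble of gene loci with `gene` matching cytokine trait ids.
#' @param expression Optional named list: per gene, the cross-tissue
#'   aggregated expression `cyto_sumstats` (see [aggregate_tissues()]).
#' @param config A [pipeline_config()].
#' @return List with `rows` (result tibble) and `graph` (see
#'   [cytokine_graph()]).
#' @export
run_direction_2 <- function(cytokines, ld, loci, expression = NULL,
                            config = pipeline_config()) {
  threshold <- bonferroni_threshold(config$alpha, length(cytokines))
  names(cytokines) <- vapply(cytokines, trait_id, character(1))
  rows <- list()
  skipped <- character(0)
  for (exp_id in names(cytokines)) {
    ex <- cytokines[[exp_id]]
    locus <- loci[loci$gene == exp_id, ]
    if (nrow(locus) == 0) {
      skipped <- c(skipped, paste0(exp_id, ": no gene locus"))
      next
    }
    instr_sets <- list(
      cis_pqtl = select_cis_pqtl(ex, locus, ld, window = config$cis_window,
                                 p_max = config$p_cis_pqtl,
                                 r2_max = config$r2_max))
    if (!is.null(expression[[exp_id]])) {
      instr_sets$cis_eqtl <- select_cis_eqtl(
        ex, expression[[exp_id]], locus, ld, window = config$cis_window,
        p_expr_max = config$p_cis_eqtl_expr,
        p_cyt_max = config$p_cis_eqtl_cyt, r2_max = config$r2_max)
    }
    for (crit in names(instr_sets)) {
      instr <- instr_sets[[crit]]
      if (nrow(instr) == 0) {
        skipped <- c(skipped, paste0(exp_id, " (", crit, "): no instruments"))
        next
      }
      for (out_id in setdiff(names(cytokines), exp_id)) {
        res <- mr_for_instruments(instr, cytokines[[out_id]], config)
        if (is.null(res)) next
        main_p <- res[[1]]$p
        cl <- NULL
        if (main_p < threshold) {
          cl <- coloc_at_locus(ex, cytokines[[out_id]], locus, config)
        }
        rows[[length(rows) + 1]] <-
          result_row(exp_id, out_id, crit, res, threshold, coloc = cl)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold") <- threshold
  attr(out, "skipped") <- skipped
  list(rows = out, graph = cytokine_graph(out, threshold))
}

#' Build the directed cytokine-on-cytokine graph
#'
#' Edges are the significant result rows (main MR `p` below the family
#' threshold); each carries the beta, p-value, selection criterion and a
#' colocalisation-support flag. Community labels come from greedy
#' modularity maximisation on the undirected projection with `|beta|` edge
#' weights (parallel edges between the same pair collapse to their maximum
#' weight); isolated configurations get singleton communities.
#'
#' @param rows Result tibble from [run_direction_2()].
#' @param threshold Family p threshold used for the edge rule.
#' @return List of class `cytokine_graph` with `edges` (tibble),
#'   `communities` (tibble `node`, `community`) and `igraph` (the directed
#'   igraph object).
#' @export
cytokine_graph <- function(rows, threshold) {
  edges <- rows[rows$significant, c("exposure", "outcome", "criterion",
                                    "beta", "p", "coloc_supported")]
  nodes <- sort(unique(c(edges$exposure, edges$outcome)))
  if (nrow(edges) == 0) {
    return(structure(list(edges = edges,
                          communities = tibble::tibble(node = character(),
                                                       community = integer()),
                          igraph = igraph::make_empty_graph()),
                     class = "cytokine_graph"))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("exposure", "outcome")], directed = TRUE,
    vertices = data.frame(name = nodes))
  igraph::E(g)$weight <- abs(edges$beta)
  und <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "max"))
  comm <- igraph::cluster_fast_greedy(und,
                                      weights = igraph::E(und)$weight)
  communities <- tibble::tibble(node = igraph::V(und)$name,
                                community = as.integer(
                                  igraph::membership(comm)))
  communities <- communities[order(communities$node), ]
  structure(list(edges = edges, communities = communities, igraph = g),
            class = "cytokine_graph")
}

#' @export
print.cytokine_graph <- function(x, ...) {
  cat("<cytokine graph> ", nrow(x$edges), " edge(s), ",
      nrow(x$communities), " node(s), ",
      length(unique(x$communities$community)), " communit(y/ies)\n",
      sep = "")
  invisible(x)
}

#' Direction 3: cytokines on cardiometabolic outcomes
#'
#' For each cytokine and each instrument criterion (cis-pQTL, cis-eQTL
#' where expression is available, and genome-wide), runs MR against every
#' cardiometabolic outcome. The family threshold is Bonferroni-corrected
#' for the number of outcomes; colocalisation at the exposure gene locus is
#' attempted for pairs with nominal MR evidence (`p < coloc_nominal_p`),
#' and binary outcomes are additionally reported as odds ratios per 1 SD of
#' the exposure.
#'
#' @param cytokines List of `cyto_sumstats`.
#' @param outcomes List of `cyto_sumstats` (quantitative or binary).
#' @param ld LD correlation matrix.
#' @param loci Gene-locus tibble.
#' @param expression Optional named list of aggregated expression
#'   `cyto_sumstats` per gene.
#' @param config A [pipeline_config()].
#' @return Tibble of result rows with the family threshold attribute.
#' @export
run_direction_3 <- function(cytokines, outcomes, ld, loci,
                            expression = NULL,
                            config = pipeline_config()) {
  threshold <- bonferroni_threshold(config$alpha, length(outcomes))
  names(cytokines) <- vapply(cytokines, trait_id, character(1))
  names(outcomes) <- vapply(outcomes, trait_id, character(1))
  rows <- list()
  skipped <- character(0)
  for (exp_id in names(cytokines)) {
    ex <- cytokines[[exp_id]]
    locus <- loci[loci$gene == exp_id, ]
    instr_sets <- list()
    if (nrow(locus) > 0) {
      instr_sets$cis_pqtl <- select_cis_pqtl(
        ex, locus, ld, window = config$cis_window,
        p_max = config$p_cis_pqtl, r2_max = config$r2_max)
      if (!is.null(expression[[exp_id]])) {
        instr_sets$cis_eqtl <- select_cis_eqtl(
          ex, expression[[exp_id]], locus, ld, window = config$cis_window,
          p_expr_max = config$p_cis_eqtl_expr,
          p_cyt_max = config$p_cis_eqtl_cyt, r2_max = config$r2_max)
      }
    }
    instr_sets$genomewide_cytokine <- select_genomewide_cytokine(
      ex, ld, p_max = config$p_genomewide, r2_max = config$r2_max)
    for (crit in names(instr_sets)) {
      instr <- instr_sets[[crit]]
      if (nrow(instr) == 0) {
        skipped <- c(skipped, paste0(exp_id, " (", crit, "): no instruments"))
        next
      }
      for (out_id in names(outcomes)) {
        oc <- outcomes[[out_id]]
        binary <- identical(trait_type(oc), "binary")
        res <- mr_for_instruments(instr, oc, config)
        if (is.null(res)) next
        cl <- NULL
        if (res[[1]]$p < config$coloc_nominal_p && nrow(locus) > 0) {
          cl <- coloc_at_locus(ex, oc, locus, config,
                               outcome_binary = binary)
        }
        rows[[length(rows) + 1]] <-
          result_row(exp_id, out_id, crit, res, threshold, coloc = cl,
                     outcome_binary = binary)
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "threshold") <- threshold
  attr(out, "skipped") <- skipped
  out
}

#' Compare MR estimates obtained under two instrument criteria
#'
#' Pearson correlation between the main-method betas of exposure-outcome
#' pairs analysed under both criteria, the similarity measure used to
#' contrast cis-pQTL with cis-eQTL instrument selection.
#'
#' @param rows_a,rows_b Result tibbles (e.g. the cis-pQTL and cis-eQTL rows
#'   of one direction).
#' @return List with `r` (Pearson correlation) and `n_pairs`.
#' @export
compare_criteria <- function(rows_a, rows_b) {
  j <- dplyr::inner_join(
    tibble::as_tibble(rows_a)[, c("exposure", "outcome", "beta")],
    tibble::as_tibble(rows_b)[, c("exposure", "outcome", "beta")],
    by = c("exposure", "outcome"), suffix = c("_a", "_b"))
  if (nrow(j) < 3) {
    stop("need >= 3 shared exposure-outcome pairs, got ", nrow(j),
         call. = FALSE)
  }
  list(r = stats::cor(j$beta_a, j$beta_b), n_pairs = nrow(j))
}

#' Z-score matrix of MR results (exposures x outcomes)
#'
#' @param rows A result tibble from any direction.
#' @return A wide tibble, exposures in rows, outcomes in columns, cells
#'   holding the main-method z score (`beta/se`).
#' @export
z_matrix <- function(rows) {
  tibble::as_tibble(rows)[, c("exposure", "outcome", "z")] |>
    tidyr::pivot_wider(names_from = "outcome", values_from = "z")
}
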