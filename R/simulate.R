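#' Configure a synthetic cohort
#'
#' Defines the genetic architecture and causal structure of a simulated
#' cohort: genotypes with block linkage disequilibrium (LD), quantitative /
#' binary / cytokine phenotypes with configurable variant effects, direct
#' (pleiotropic) effects, trait-on-trait causal effects, and per-tissue gene
#' expression. The generator gives every downstream pipeline stage a data
#' source with known ground truth.
#'
#' Haplotypes are drawn from a Gaussian copula: within each LD block of
#' `ld_block_size` adjacent variants, latent normals have correlation
#' `ld_rho^|i - j|`; each latent value is thresholded at the variant's
#' minor-allele-frequency quantile to give a 0/1 allele, and two independent
#' haplotypes sum to the dosage. Blocks are mutually independent.
#'
#' @param n_individuals,n_variants Cohort and panel sizes.
#' @param ld_block_size Number of adjacent variants per LD block.
#' @param ld_rho Adjacent-variant latent correlation in \[0, 1); decays as
#'   `ld_rho^distance` within a block.
#' @param maf_range Minor-allele-frequency range, a sub-interval of (0, 0.5].
#' @param traits Tibble describing the phenotypes: columns `trait_id`,
#'   `type` (`"cytokine"`, `"quantitative"` or `"binary"`), `noise_sd`
#'   (residual standard deviation) and `prevalence` (binary traits only,
#'   `NA` otherwise).
#' @param causal_map Tibble of direct variant effects: columns `trait_id`,
#'   `variant` (index into the panel), `beta` (per-allele effect, trait SD
#'   units). Direct pleiotropic variant-on-outcome effects are expressed the
#'   same way, as extra rows for the outcome trait.
#' @param trait_dag Tibble of trait-on-trait causal effects: columns `from`,
#'   `to`, `beta` (SD units). Must be acyclic.
#' @param gene_loci Tibble of gene windows (see [gene_locus()]) for
#'   expression simulation and cis instrument selection.
#' @param expression_map Tibble of cis effects on expression: columns
#'   `gene`, `variant`, `beta_shared` (effect common to all tissues) and
#'   `beta_tissue_sd` (SD of the tissue-specific effect component).
#' @param n_tissues Number of tissues for expression phenotypes.
#' @param expression_noise_sd Residual SD of each (gene, tissue) expression
#'   value.
#' @param pos_spacing Base-pair spacing between adjacent panel variants
#'   (all variants are placed on one chromosome).
#' @param seed Integer seed; fixing it makes every simulated value
#'   reproducible.
#' @param panel_seed Separate seed for the variant panel (MAFs and allele
#'   labels). Two configurations sharing `panel_seed` but differing in
#'   `seed` simulate independent cohorts genotyped on the same panel, the
#'   natural two-sample MR design. Defaults to `seed`.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals, n_variants, ld_block_size = 10L,
                       ld_rho = 0, maf_range = c(0.05, 0.5),
                       traits = NULL, causal_map = NULL, trait_dag = NULL,
                       gene_loci = NULL, expression_map = NULL,
                       n_tissues = 1L, expression_noise_sd = 1,
                       pos_spacing = 1000L, seed = 1L, panel_seed = NULL) {
  stopifnot(n_individuals >= 2, n_variants >= 1, ld_block_size >= 1,
            ld_rho >= 0, ld_rho < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  traits <- traits %||%
    tibble::tibble(trait_id = character(), type = character(),
                   noise_sd = numeric(), prevalence = numeric())
  if (!"prevalence" %in% names(traits)) traits$prevalence <- NA_real_
  if (!"noise_sd" %in% names(traits)) traits$noise_sd <- 1
  causal_map <- causal_map %||%
    tibble::tibble(trait_id = character(), variant = integer(),
                   beta = numeric())
  trait_dag <- trait_dag %||%
    tibble::tibble(from = character(), to = character(), beta = numeric())
  expression_map <- expression_map %||%
    tibble::tibble(gene = character(), variant = integer(),
                   beta_shared = numeric(), beta_tissue_sd = numeric())
  if (nrow(causal_map) > 0 &&
      any(causal_map$variant < 1 | causal_map$variant > n_variants)) {
    stop("causal_map variant index out of range", call. = FALSE)
  }
  if (nrow(expression_map) > 0 &&
      any(expression_map$variant < 1 | expression_map$variant > n_variants)) {
    stop("expression_map variant index out of range", call. = FALSE)
  }
  if (nrow(trait_dag) > 0) {
    g <- igraph::graph_from_data_frame(trait_dag[, c("from", "to")])
    if (!igraph::is_dag(g)) stop("trait_dag must be acyclic", call. = FALSE)
  }
  structure(list(
    n_individuals = as.integer(n_individuals),
    n_variants = as.integer(n_variants),
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    maf_range = maf_range, traits = traits, causal_map = causal_map,
    trait_dag = trait_dag, gene_loci = gene_loci,
    expression_map = expression_map, n_tissues = as.integer(n_tissues),
    expression_noise_sd = expression_noise_sd,
    pos_spacing = as.integer(pos_spacing), seed = as.integer(seed),
    panel_seed = as.integer(panel_seed %||% seed)
  ), class = "sim_config")
}

# Cholesky factor of the AR(1) block correlation, reused across blocks.
ar1_chol <- function(size, rho) {
  if (size == 1 || rho == 0) return(diag(size))
  s <- rho^abs(outer(seq_len(size), seq_len(size), "-"))
  chol(s)
}

# One haplotype matrix (individuals x variants) of 0/1 alleles under the
# block-AR(1) Gaussian copula thresholded at each variant's MAF quantile.
draw_haplotypes <- function(n, mafs, block_size, rho) {
  m <- length(mafs)
  z <- matrix(rnorm(n * m), nrow = n, ncol = m)
  if (rho > 0 && block_size > 1) {
    starts <- seq(1L, m, by = block_size)
    for (s in starts) {
      e <- min(s + block_size - 1L, m)
      len <- e - s + 1L
      if (len > 1) {
        z[, s:e] <- z[, s:e] %*% ar1_chol(len, rho)
      }
    }
  }
  thresh <- qnorm(mafs)
  t(z) < thresh   # variants x individuals
}

#' Simulate a cohort from a configuration
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `dosages` (variants x
#'   individuals, values 0/1/2), `variants` (tibble of variant id, chrom,
#'   pos, effect/other allele, MAF), `phenotypes` (named list of per-trait
#'   vectors; binary traits are 0/1), `liability` (underlying quantitative
#'   scale of each trait, before any binary thresholding), `expression`
#'   (per gene, an individuals x tissues matrix) and the `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_individuals
  m <- config$n_variants
  # the variant panel is seeded separately so that independent cohorts can
  # share identical MAFs and allele labels
  panel <- withr::with_seed(config$panel_seed, {
    mafs <- runif(m, config$maf_range[1], config$maf_range[2])
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample.int(nrow(pairs), m, replace = TRUE)
    list(mafs = mafs, ea = pairs[pick, 1], oa = pairs[pick, 2])
  })
  withr::with_seed(config$seed, {
    mafs <- panel$mafs
    dos <- draw_haplotypes(n, mafs, config$ld_block_size, config$ld_rho) +
      draw_haplotypes(n, mafs, config$ld_block_size, config$ld_rho)
    storage.mode(dos) <- "double"
    variants <- tibble::tibble(
      variant_id = paste0("rs", seq_len(m)),
      chrom = "1",
      pos = seq_len(m) * config$pos_spacing,
      ea = panel$ea, oa = panel$oa,
      maf = mafs
    )
    rownames(dos) <- variants$variant_id

    # traits in topological order of the DAG
    trait_ids <- config$traits$trait_id
    order_ids <- trait_ids
    if (nrow(config$trait_dag) > 0) {
      g <- igraph::graph_from_data_frame(
        config$trait_dag[, c("from", "to")],
        vertices = data.frame(name = trait_ids))
      order_ids <- igraph::topo_sort(g, mode = "out")$name
    }
    liability <- list()
    phenotypes <- list()
    for (tid in order_ids) {
      row <- config$traits[config$traits$trait_id == tid, ]
      y <- rep(0, n)
      cm <- config$causal_map[config$causal_map$trait_id == tid, ]
      if (nrow(cm) > 0) {
        y <- y + as.vector(crossprod(dos[cm$variant, , drop = FALSE], cm$beta))
      }
      dag_in <- config$trait_dag[config$trait_dag$to == tid, ]
      if (nrow(dag_in) > 0) {
        for (k in seq_len(nrow(dag_in))) {
          y <- y + dag_in$beta[k] * liability[[dag_in$from[k]]]
        }
      }
      y <- y + rnorm(n, sd = row$noise_sd)
      liability[[tid]] <- y
      if (row$type == "binary") {
        thr <- quantile(y, 1 - row$prevalence, names = FALSE)
        phenotypes[[tid]] <- as.integer(y > thr)
      } else {
        phenotypes[[tid]] <- y
      }
    }

    # expression: per gene an individuals x tissues matrix
    expression <- list()
    genes <- unique(config$expression_map$gene)
    for (g in genes) {
      em <- config$expression_map[config$expression_map$gene == g, ]
      mat <- matrix(0, nrow = n, ncol = config$n_tissues)
      for (k in seq_len(nrow(em))) {
        d <- dos[em$variant[k], ]
        eff <- em$beta_shared[k] +
          rnorm(config$n_tissues, sd = em$beta_tissue_sd[k])
        mat <- mat + outer(d, eff)
      }
      mat <- mat + matrix(rnorm(n * config$n_tissues,
                                sd = config$expression_noise_sd),
                          nrow = n)
      colnames(mat) <- paste0("tissue", seq_len(config$n_tissues))
      expression[[g]] <- mat
    }

    structure(list(dosages = dos, variants = variants,
                   phenotypes = phenotypes, liability = liability,
                   expression = expression, config = config),
              class = "sim_cohort")
  })
}

#' True causal effects of a simulation configuration
#'
#' @param config A [sim_config()].
#' @return Tibble (`trait_id`, `variant_id`, `beta`) of the configured
#'   direct variant effects, for checking recovery in test harnesses.
#' @export
sim_truth <- function(config) {
  cm <- config$causal_map
  tibble::tibble(trait_id = cm$trait_id,
                 variant_id = paste0("rs", cm$variant),
                 beta = cm$beta)
}

#' Rank-based inverse normal transform
#'
#' Maps rank r of m values to `qnorm((r - 3/8) / (m + 1/4))` (the Blom
#' offset); ties share the average rank. Standard preprocessing for cytokine
#' concentrations before GWAS.
#'
#' @param values Numeric vector, length >= 2, not constant.
#' @return Transformed vector with mean ~0 for tie-free input.
#' @export
inverse_normal_transform <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (length(unique(values)) == 1) {
    stop("cannot transform a constant vector", call. = FALSE)
  }
  r <- rank(values, ties.method = "average")
  qnorm((r - 0.375) / (length(values) + 0.25))
}

# Vectorised per-variant OLS of y on each dosage row (plus covariates via
# Frisch-Waugh residualisation). Returns beta, se, p per variant.
gwas_ols <- function(dosages, y, covariates = NULL) {
  n <- length(y)
  if (!is.null(covariates)) {
    cc <- cbind(1, covariates)
    qr_c <- qr(cc)
    y <- qr.resid(qr_c, y)
    dosages <- t(qr.resid(qr_c, t(dosages)))
    df <- n - ncol(cc) - 1L
  } else {
    y <- y - mean(y)
    dosages <- dosages - rowMeans(dosages)
    df <- n - 2L
  }
  sxx <- rowSums(dosages^2)
  sxy <- as.vector(dosages %*% y)
  syy <- sum(y^2)
  mono <- sxx <= .Machine$double.eps * n
  beta <- ifelse(mono, 0, sxy / sxx)
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- ifelse(mono, Inf, sqrt(rss / df / sxx))
  z <- ifelse(is.finite(se) & se > 0, beta / se, 0)
  p <- pmin(2 * pnorm(-abs(z)), 1)
  p[mono] <- 1
  list(beta = unname(beta), se = unname(se), p = unname(p))
}

# Per-variant logistic regression (Wald test).
gwas_logistic <- function(dosages, y, covariates = NULL) {
  m <- nrow(dosages)
  beta <- se <- p <- numeric(m)
  base <- if (is.null(covariates)) matrix(1, length(y), 1) else
    cbind(1, covariates)
  for (j in seq_len(m)) {
    g <- dosages[j, ]
    if (stats::var(g) <= .Machine$double.eps) {
      beta[j] <- 0; se[j] <- Inf; p[j] <- 1
      next
    }
    fit <- suppressWarnings(
      stats::glm.fit(cbind(base, g), y, family = stats::binomial()))
    cf <- fit$coefficients
    k <- length(cf)
    # Wald se from the weighted cross-product inverse
    w <- fit$weights
    xw <- cbind(base, g) * sqrt(w)
    vc <- tryCatch(solve(crossprod(xw)), error = function(e) NULL)
    if (is.null(vc) || !is.finite(cf[k])) {
      beta[j] <- 0; se[j] <- Inf; p[j] <- 1
    } else {
      beta[j] <- cf[k]
      se[j] <- sqrt(vc[k, k])
      p[j] <- min(2 * pnorm(-abs(beta[j] / se[j])), 1)
    }
  }
  list(beta = beta, se = se, p = p)
}

#' Run a per-variant additive-model GWAS on a simulated cohort
#'
#' Quantitative traits are analysed by linear regression of the (optionally
#' inverse-normal transformed) phenotype on dosage, binary traits by
#' logistic regression; both report the Wald statistic's two-sided normal
#' p-value. Monomorphic variants are emitted with `beta = 0`, `se = Inf`,
#' `p = 1` so that downstream selection excludes them.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param trait Trait id present in the cohort, or `"expr:<gene>:<tissue>"`
#'   for an expression phenotype.
#' @param covariates Optional numeric matrix (individuals x covariates).
#' @param inverse_normal Transform the phenotype first? Defaults to `TRUE`
#'   for cytokine traits, `FALSE` otherwise.
#' @param variants Optional integer or character index restricting the scan
#'   to a subset of panel variants.
#'
#' @return A `cyto_sumstats` tibble with `eaf = mean(dosage) / 2`.
#' @export
run_gwas <- function(cohort, trait, covariates = NULL,
                     inverse_normal = NULL, variants = NULL) {
  stopifnot(inherits(cohort, "sim_cohort"))
  cfg <- cohort$config
  if (grepl("^expr:", trait)) {
    parts <- strsplit(trait, ":", fixed = TRUE)[[1]]
    gene <- parts[2]; tissue <- parts[3]
    if (is.null(cohort$expression[[gene]])) {
      stop("gene ", gene, " not simulated", call. = FALSE)
    }
    y <- cohort$expression[[gene]][, tissue]
    type <- "expression"
  } else {
    if (is.null(cohort$phenotypes[[trait]])) {
      stop("trait ", trait, " not present in cohort", call. = FALSE)
    }
    y <- cohort$phenotypes[[trait]]
    type <- cfg$traits$type[cfg$traits$trait_id == trait]
    tissue <- NULL
  }
  dos <- cohort$dosages
  vtbl <- cohort$variants
  if (!is.null(variants)) {
    dos <- dos[variants, , drop = FALSE]
    vtbl <- vtbl[match(rownames(dos), vtbl$variant_id), ]
  }
  if (type == "binary") {
    stopifnot(all(y %in% c(0, 1)))
    res <- gwas_logistic(dos, y, covariates)
  } else {
    if (is.null(inverse_normal)) inverse_normal <- type == "cytokine"
    if (inverse_normal) y <- inverse_normal_transform(y)
    res <- gwas_ols(dos, y, covariates)
  }
  sumstats(tibble::tibble(
    variant_id = vtbl$variant_id, chrom = vtbl$chrom, pos = vtbl$pos,
    ea = vtbl$ea, oa = vtbl$oa,
    eaf = rowMeans(dos) / 2,
    beta = res$beta, se = res$se, p = res$p,
    n = length(y)
  ), trait_id = if (type == "expression") gene else trait,
    trait_type = if (type == "expression") "expression" else type,
    tissue = if (type == "expression") tissue else NULL)
}
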