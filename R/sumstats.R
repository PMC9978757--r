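#' @importFrom rlang .data %||%
#' @importFrom stats pnorm qnorm rnorm rbinom runif cor sd quantile setNames
NULL

# Default column names for summary-statistics files.
sumstats_default_cols <- c(
  variant_id = "SNP", chrom = "CHR", pos = "POS", ea = "EA", oa = "OA",
  eaf = "EAF", beta = "BETA", se = "SE", p = "P", n = "N"
)

#' Construct a GWAS summary-statistics table
#'
#' A summary-statistics object is a tibble with one row per variant and
#' columns `variant_id`, `chrom`, `pos`, `ea` (effect allele), `oa` (other
#' allele), `eaf` (effect-allele frequency), `beta`, `se`, `p`, `n`, carrying
#' the trait's identity as attributes. `beta` is per effect-allele copy, in
#' standard-deviation units of the trait for quantitative traits and log-odds
#' for binary traits.
#'
#' @param x Data frame with the columns above.
#' @param trait_id Trait identifier string.
#' @param trait_type One of `"cytokine"`, `"quantitative"`, `"binary"`,
#'   `"expression"`.
#' @param tissue Tissue label; required when `trait_type = "expression"`.
#' @param report Optional named integer vector of row-drop counts.
#'
#' @return A tibble of class `cyto_sumstats`.
#' @export
sumstats <- function(x, trait_id, trait_type = "quantitative", tissue = NULL,
                     report = NULL) {
  trait_type <- match.arg(trait_type,
                          c("cytokine", "quantitative", "binary", "expression"))
  if (trait_type == "expression" && is.null(tissue)) {
    stop("expression summary statistics require a `tissue` label", call. = FALSE)
  }
  needed <- names(sumstats_default_cols)
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(x)[needed]
  out$variant_id <- as.character(out$variant_id)
  out$chrom <- as.character(out$chrom)
  out$pos <- as.integer(out$pos)
  out$ea <- toupper(as.character(out$ea))
  out$oa <- toupper(as.character(out$oa))
  out$n <- as.integer(out$n)
  if (anyDuplicated(out$variant_id) > 0) {
    stop("duplicate variant_id in summary statistics for trait ", trait_id,
         call. = FALSE)
  }
  structure(out,
            class = c("cyto_sumstats", class(tibble::tibble())),
            trait_id = trait_id, trait_type = trait_type, tissue = tissue,
            report = report)
}

#' @export
print.cyto_sumstats <- function(x, ...) {
  cat("<GWAS summary statistics> trait: ", attr(x, "trait_id"),
      " (", attr(x, "trait_type"),
      if (!is.null(attr(x, "tissue"))) paste0(", tissue ", attr(x, "tissue")),
      "), ", nrow(x), " variants\n", sep = "")
  NextMethod()
}

#' Trait metadata accessors
#'
#' @param x A `cyto_sumstats` object.
#' @return `trait_id()` and `trait_type()` return strings; `drop_report()`
#'   returns the named count vector recorded when rows were filtered, or
#'   `NULL`.
#' @export
trait_id <- function(x) attr(x, "trait_id")

#' @rdname trait_id
#' @export
trait_type <- function(x) attr(x, "trait_type")

#' @rdname trait_id
#' @export
drop_report <- function(x) attr(x, "report")

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab-separated table (gzip-transparent) with one header row. Rows
#' with missing or invalid required fields (non-positive `se`, `p` outside
#' (0, 1], `eaf` outside (0, 1), identical alleles) are dropped and counted
#' in the attached report (see [drop_report()]).
#'
#' @param path File path.
#' @param trait_id,trait_type,tissue Trait metadata, see [sumstats()].
#' @param column_map Named character vector mapping internal field names
#'   (`variant_id`, `chrom`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `p`, `n`)
#'   to the file's column names. Defaults to the conventional
#'   SNP/CHR/POS/EA/OA/EAF/BETA/SE/P/N header.
#'
#' @return A `cyto_sumstats` tibble.
#' @export
read_sumstats <- function(path, trait_id, trait_type = "quantitative",
                          tissue = NULL, column_map = sumstats_default_cols) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(unname(column_map), names(raw))
  if (length(missing_cols) > 0) {
    stop("input file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::tibble(
    variant_id = raw[[column_map[["variant_id"]]]],
    chrom = raw[[column_map[["chrom"]]]],
    pos = suppressWarnings(as.integer(raw[[column_map[["pos"]]]])),
    ea = toupper(raw[[column_map[["ea"]]]]),
    oa = toupper(raw[[column_map[["oa"]]]]),
    eaf = suppressWarnings(as.numeric(raw[[column_map[["eaf"]]]])),
    beta = suppressWarnings(as.numeric(raw[[column_map[["beta"]]]])),
    se = suppressWarnings(as.numeric(raw[[column_map[["se"]]]])),
    p = suppressWarnings(as.numeric(raw[[column_map[["p"]]]])),
    n = suppressWarnings(as.integer(raw[[column_map[["n"]]]]))
  )
  bad_missing <- !stats::complete.cases(tbl)
  ok <- !bad_missing
  bad_se <- ok & tbl$se <= 0
  bad_p <- ok & (tbl$p <= 0 | tbl$p > 1)
  bad_eaf <- ok & (tbl$eaf <= 0 | tbl$eaf >= 1)
  bad_pos <- ok & tbl$pos < 1
  bad_alleles <- ok & (tbl$ea == tbl$oa |
                         !grepl("^[ACGT]+$", tbl$ea) |
                         !grepl("^[ACGT]+$", tbl$oa))
  report <- c(missing = sum(bad_missing), invalid_se = sum(bad_se),
              invalid_p = sum(bad_p), invalid_eaf = sum(bad_eaf),
              invalid_pos = sum(bad_pos), invalid_alleles = sum(bad_alleles))
  keep <- ok & !(bad_se | bad_p | bad_eaf | bad_pos | bad_alleles)
  if (!any(keep)) {
    stop("no valid rows in ", path, call. = FALSE)
  }
  sumstats(tbl[keep, ], trait_id = trait_id, trait_type = trait_type,
           tissue = tissue, report = report)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Numeric fields are written at full (shortest round-trip) precision, so a
#' write/read cycle reproduces every value exactly.
#'
#' @param x A `cyto_sumstats` tibble.
#' @param path Output path; a `.gz` suffix compresses transparently.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(x, path) {
  out <- tibble::tibble(
    SNP = x$variant_id, CHR = x$chrom, POS = x$pos, EA = x$ea, OA = x$oa,
    EAF = x$eaf, BETA = x$beta, SE = x$se, P = x$p, N = x$n
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read gene loci from a BED file
#'
#' BED coordinates are 0-based half-open; they are converted to the 1-based
#' inclusive convention used throughout the package.
#'
#' @param path BED file path (columns: chrom, start, end, name).
#' @return Tibble with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_loci <- function(path) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 4) {
    stop("BED file must have at least 4 columns (chrom, start, end, name)",
         call. = FALSE)
  }
  tibble::tibble(
    gene = as.character(raw[[4]]),
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]) + 1L,
    end = as.integer(raw[[3]])
  )
}

#' Define a gene locus
#'
#' @param gene Gene name.
#' @param chrom Chromosome.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return One-row tibble.
#' @export
gene_locus <- function(gene, chrom, start, end) {
  stopifnot(start <= end, start >= 1)
  tibble::tibble(gene = gene, chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(end))
}

allele_complement <- function(a) {
  chartr("ACGT", "TGCA", a)
}

is_palindromic <- function(ea, oa) {
  ea == allele_complement(oa)
}

#' Harmonise exposure and outcome summary statistics
#'
#' Aligns two traits' association records to a common effect allele, the
#' input required by every two-sample MR estimator. Variants are matched on
#' (chromosome, position); allele labels are then reconciled, allowing for
#' swapped effect/other alleles and for strand flips. When the outcome's
#' alleles are swapped relative to the exposure, the outcome beta changes
#' sign and its effect-allele frequency becomes `1 - eaf`.
#'
#' Palindromic variants (A/T or C/G) cannot be strand-resolved from allele
#' labels alone; they are retained only when both traits' effect-allele
#' frequencies lie on the same side of 0.5 and the minor-allele frequency is
#' below `palindrome_eaf_limit`, and dropped otherwise. Indels and positions
#' carrying more than one variant are dropped.
#'
#' @param exposure,outcome `cyto_sumstats` tibbles.
#' @param palindrome_eaf_limit Frequency cut-off in (0, 0.5] for retaining
#'   palindromic variants (default 0.42).
#'
#' @return A tibble of class `cyto_harmonised` with columns `variant_id`,
#'   `chrom`, `pos`, `ea`, `oa`, `eaf_exp`, `beta_exp`, `se_exp`, `p_exp`,
#'   `eaf_out`, `beta_out`, `se_out`, `p_out`, `n_exp`, `n_out`; attributes
#'   `exposure_id`, `outcome_id` and a `report` of drop reasons.
#' @export
harmonise <- function(exposure, outcome, palindrome_eaf_limit = 0.42) {
  stopifnot(palindrome_eaf_limit > 0, palindrome_eaf_limit <= 0.5)
  exp_tbl <- tibble::as_tibble(exposure)
  out_tbl <- tibble::as_tibble(outcome)

  # indels / multi-allelic positions out first
  snv <- function(tbl) nchar(tbl$ea) == 1L & nchar(tbl$oa) == 1L
  n_indel <- sum(!snv(exp_tbl)) + sum(!snv(out_tbl))
  exp_tbl <- exp_tbl[snv(exp_tbl), ]
  out_tbl <- out_tbl[snv(out_tbl), ]
  dup_key <- function(tbl) paste(tbl$chrom, tbl$pos)
  dups_e <- dup_key(exp_tbl) %in% dup_key(exp_tbl)[duplicated(dup_key(exp_tbl))]
  dups_o <- dup_key(out_tbl) %in% dup_key(out_tbl)[duplicated(dup_key(out_tbl))]
  n_multi <- sum(dups_e) + sum(dups_o)
  exp_tbl <- exp_tbl[!dups_e, ]
  out_tbl <- out_tbl[!dups_o, ]

  j <- dplyr::inner_join(exp_tbl, out_tbl, by = c("chrom", "pos"),
                         suffix = c("_exp", "_out"))
  if (nrow(j) == 0) {
    stop("no shared variants between ", trait_id(exposure), " and ",
         trait_id(outcome), call. = FALSE)
  }

  ea_e <- j$ea_exp; oa_e <- j$oa_exp
  ea_o <- j$ea_out; oa_o <- j$oa_out
  pal <- is_palindromic(ea_e, oa_e)

  same <- ea_o == ea_e & oa_o == oa_e
  swap <- ea_o == oa_e & oa_o == ea_e
  flip <- !pal & allele_complement(ea_o) == ea_e & allele_complement(oa_o) == oa_e
  flip_swap <- !pal & allele_complement(ea_o) == oa_e &
    allele_complement(oa_o) == ea_e

  # orientation: +1 keep outcome as-is, -1 negate beta_out and reflect eaf
  orient <- rep(NA_real_, nrow(j))
  orient[same | flip] <- 1
  orient[(swap | flip_swap) & is.na(orient)] <- -1
  irreconcilable <- is.na(orient) & !(pal & (same | swap))

  # palindromic: after label alignment, both traits' EAF must agree in side
  # of 0.5 and the variant must be clearly non-ambiguous (MAF < limit)
  eaf_out_aligned <- ifelse(orient == -1, 1 - j$eaf_out, j$eaf_out)
  pal_keep <- pal & !is.na(orient) &
    ((j$eaf_exp - 0.5) * (eaf_out_aligned - 0.5) > 0) &
    pmin(j$eaf_exp, 1 - j$eaf_exp) < palindrome_eaf_limit &
    pmin(eaf_out_aligned, 1 - eaf_out_aligned) < palindrome_eaf_limit
  drop_pal <- pal & !pal_keep

  keep <- !irreconcilable & !drop_pal
  report <- c(indel = n_indel, multiallelic = n_multi,
              irreconcilable = sum(irreconcilable, na.rm = TRUE),
              palindromic_ambiguous = sum(drop_pal, na.rm = TRUE))
  j <- j[keep, ]
  orient <- orient[keep]
  if (nrow(j) == 0) {
    stop("no harmonisable variants between ", trait_id(exposure), " and ",
         trait_id(outcome), call. = FALSE)
  }

  res <- tibble::tibble(
    variant_id = j$variant_id_exp,
    chrom = j$chrom, pos = j$pos,
    ea = j$ea_exp, oa = j$oa_exp,
    eaf_exp = j$eaf_exp, beta_exp = j$beta_exp, se_exp = j$se_exp,
    p_exp = j$p_exp, n_exp = j$n_exp,
    eaf_out = ifelse(orient == -1, 1 - j$eaf_out, j$eaf_out),
    beta_out = orient * j$beta_out, se_out = j$se_out, p_out = j$p_out,
    n_out = j$n_out
  )
  structure(res,
            class = c("cyto_harmonised", class(tibble::tibble())),
            exposure_id = trait_id(exposure), outcome_id = trait_id(outcome),
            report = report)
}

#' Build a harmonised exposure/outcome set directly from aligned effects
#'
#' Convenience constructor used when effects are already on a common effect
#' allele (for example simulation output); skips the matching logic of
#' [harmonise()].
#'
#' @param beta_exp,se_exp,beta_out,se_out Numeric vectors of equal length;
#'   standard errors must be positive.
#' @param exposure_id,outcome_id Trait labels.
#' @param variant_id Optional variant identifiers.
#' @return A `cyto_harmonised` tibble.
#' @export
harmonised_set <- function(beta_exp, se_exp, beta_out, se_out,
                           exposure_id = "exposure", outcome_id = "outcome",
                           variant_id = NULL) {
  m <- length(beta_exp)
  stopifnot(length(se_exp) == m, length(beta_out) == m, length(se_out) == m,
            all(se_exp > 0), all(se_out > 0))
  res <- tibble::tibble(
    variant_id = variant_id %||% paste0("v", seq_len(m)),
    chrom = "1", pos = seq_len(m), ea = "A", oa = "G",
    eaf_exp = NA_real_, beta_exp = beta_exp, se_exp = se_exp,
    p_exp = 2 * pnorm(-abs(beta_exp / se_exp)), n_exp = NA_integer_,
    eaf_out = NA_real_, beta_out = beta_out, se_out = se_out,
    p_out = 2 * pnorm(-abs(beta_out / se_out)), n_out = NA_integer_
  )
  structure(res,
            class = c("cyto_harmonised", class(tibble::tibble())),
            exposure_id = exposure_id, outcome_id = outcome_id,
            report = NULL)
}

#' @export
print.cyto_harmonised <- function(x, ...) {
  cat("<harmonised exposure/outcome set> ", attr(x, "exposure_id"), " -> ",
      attr(x, "outcome_id"), ", ", nrow(x), " variants\n", sep = "")
  NextMethod()
}

# Reinterpret one side of a harmonised set as summary statistics (used for
# idempotence checks and for re-harmonising pipeline intermediates).
sumstats_from_harmonised <- function(h, side = c("exposure", "outcome"),
                                     trait_type = "quantitative") {
  side <- match.arg(side)
  sfx <- if (side == "exposure") "exp" else "out"
  tbl <- tibble::tibble(
    variant_id = h$variant_id, chrom = h$chrom, pos = h$pos,
    ea = h$ea, oa = h$oa,
    eaf = h[[paste0("eaf_", sfx)]], beta = h[[paste0("beta_", sfx)]],
    se = h[[paste0("se_", sfx)]], p = h[[paste0("p_", sfx)]],
    n = h[[paste0("n_", sfx)]]
  )
  id <- attr(h, if (side == "exposure") "exposure_id" else "outcome_id")
  sumstats(tbl, trait_id = id, trait_type = trait_type)
}

#' Compute an LD correlation matrix from genotype dosages
#'
#' @param dosages Numeric matrix, variants in rows and individuals in
#'   columns, values in \[0, 2\]. Row names become the variant labels.
#' @return Square correlation matrix `r` (monomorphic variants get zero
#'   off-diagonal correlation and unit diagonal).
#' @export
ld_from_dosages <- function(dosages) {
  r <- suppressWarnings(stats::cor(t(dosages)))
  r[is.na(r)] <- 0
  diag(r) <- 1
  dimnames(r) <- list(rownames(dosages), rownames(dosages))
  r
}

#' Read / write a plain-text LD matrix with a variant-list sidecar
#'
#' The matrix file holds the square correlation matrix, whitespace-separated;
#' the sidecar (same path plus `.vars`) holds one variant id per line in
#' matrix order.
#'
#' @param path Matrix file path.
#' @return `read_ld()` returns the named square matrix; `write_ld()` returns
#'   `path` invisibly.
#' @export
read_ld <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  vars <- readLines(paste0(path, ".vars"))
  stopifnot(nrow(m) == ncol(m), nrow(m) == length(vars))
  dimnames(m) <- list(vars, vars)
  m
}

#' @rdname read_ld
#' @param r Square correlation matrix with variant row names.
#' @export
write_ld <- function(r, path) {
  utils::write.table(r, path, row.names = FALSE, col.names = FALSE)
  writeLines(rownames(r), paste0(path, ".vars"))
  invisible(path)
}
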