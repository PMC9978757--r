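#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR result
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return One-row tibble with `method`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`, `p.value`, `n_snp`, `role`.
#' @export
tidy.mr_result <- function(x, ...) {
  tibble::tibble(method = x$method, estimate = x$beta, std.error = x$se,
                 conf.low = x$ci_low, conf.high = x$ci_high,
                 p.value = x$p, n_snp = x$n_snp, role = x$role)
}

#' @rdname tidy.mr_result
#' @return `glance()` adds the method-specific diagnostics (heterogeneity
#'   Q, Egger intercept, PRESSO global p) as columns where present.
#' @export
glance.mr_result <- function(x, ...) {
  out <- tidy(x)
  scalars <- Filter(function(e) is.numeric(e) && length(e) == 1, x$extras)
  if (length(scalars) > 0) {
    out <- dplyr::bind_cols(out, tibble::as_tibble(scalars))
  }
  out
}

#' Tidy a list of MR results into one table
#'
#' @param results List of `mr_result` objects (e.g. from [run_mr()]).
#' @return Tibble, one row per method.
#' @export
tidy_mr_suite <- function(results) {
  dplyr::bind_rows(lapply(results, tidy))
}

#' Tidy a colocalisation result
#'
#' @param x A `coloc_result`.
#' @param ... Unused.
#' @return Tibble with one row per hypothesis and its posterior
#'   probability.
#' @export
tidy.coloc_result <- function(x, ...) {
  tibble::tibble(hypothesis = names(x$pp), posterior = unname(x$pp))
}

#' @rdname tidy.coloc_result
#' @return `glance()` returns the one-row summary: the shared/distinct
#'   posteriors, variant count and the two decision flags.
#' @export
glance.coloc_result <- function(x, ...) {
  tibble::tibble(pp_shared = x$pp_shared, pp_distinct = x$pp_distinct,
                 n_variants = x$n_variants,
                 passes_support = x$passes_support,
                 passes_ratio = x$passes_ratio)
}

#' Tidy a cytokine graph into its edge list
#'
#' @param x A `cytokine_graph`.
#' @param ... Unused.
#' @return The edge tibble joined with each endpoint's community label.
#' @export
tidy.cytokine_graph <- function(x, ...) {
  e <- x$edges
  comm <- x$communities
  e$community_exposure <- comm$community[match(e$exposure, comm$node)]
  e$community_outcome <- comm$community[match(e$outcome, comm$node)]
  e
}
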