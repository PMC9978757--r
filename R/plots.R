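#' Scatter plot of a harmonised exposure/outcome set with MR fits
#'
#' Per-variant outcome betas against exposure betas (error bars = 1 SE),
#' with one fitted line per supplied MR result (through the origin except
#' MR-Egger, whose intercept is drawn).
#'
#' @param h A `cyto_harmonised` set.
#' @param results Optional list of `mr_result` objects to overlay.
#' @return A ggplot object.
#' @export
plot_mr_scatter <- function(h, results = NULL) {
  df <- tibble::as_tibble(h)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$beta_exp,
                                        y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           width = 0, colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$beta_exp - .data$se_exp,
                                         xmax = .data$beta_exp + .data$se_exp),
                            height = 0, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNP effect on exposure", y = "SNP effect on outcome",
                  title = paste(attr(h, "exposure_id"), "→",
                                attr(h, "outcome_id")))
  if (!is.null(results)) {
    lines <- dplyr::bind_rows(lapply(results, function(r) {
      tibble::tibble(method = r$method,
                     intercept = r$extras$egger_intercept %||% 0,
                     slope = r$beta)
    }))
    p <- p + ggplot2::geom_abline(
      data = lines,
      ggplot2::aes(intercept = .data$intercept, slope = .data$slope,
                   colour = .data$method)) +
      ggplot2::labs(colour = "MR method")
  }
  p
}

#' Heat-map of MR z scores across exposure-outcome pairs
#'
#' The Figure-2-style overview: tiles coloured by the main-method z score,
#' with an asterisk where the pair passes the family significance
#' threshold.
#'
#' @param rows A result tibble from a pipeline direction.
#' @param threshold Family threshold; defaults to the tibble's `threshold`
#'   attribute.
#' @return A ggplot object.
#' @export
plot_z_matrix <- function(rows, threshold = NULL) {
  threshold <- threshold %||% attr(rows, "threshold")
  df <- tibble::as_tibble(rows)
  df$label <- ifelse(df$p < threshold, "*", "")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$exposure,
                                   fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label)) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                  high = "red") +
    ggplot2::labs(x = "Outcome", y = "Genetically proxied exposure",
                  fill = "z") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Posterior-probability bar chart for a colocalisation result
#'
#' @param x A `coloc_result`.
#' @return A ggplot object.
#' @export
plot_coloc <- function(x) {
  df <- tidy(x)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$hypothesis,
                                   y = .data$posterior)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Posterior probability")
}

#' Autoplot methods
#'
#' `autoplot()` dispatches to [plot_coloc()] for colocalisation results and
#' to a forest-style plot for a list of MR results.
#'
#' @param object A `coloc_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.coloc_result <- function(object, ...) plot_coloc(object)

#' @rdname autoplot.coloc_result
#' @export
autoplot.mr_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$method)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.1) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "Causal estimate (95% CI)", y = NULL)
}
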