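#' Plot an expected/observed FDR table
#'
#' Observed significant counts against the null expectation across
#' thresholds, one panel per scan when the combined pipeline table is
#' supplied.
#'
#' @param fdr Tibble from [fdr_table()] or the `fdr` element of a
#'   [`synergy_run`][run_pipeline].
#' @return A ggplot object.
#' @export
plot_fdr <- function(fdr) {
  df <- fdr |>
    tidyr::pivot_longer(c("n_observed", "n_expected"),
                        names_to = "kind", values_to = "count") |>
    dplyr::mutate(kind = dplyr::recode(.data$kind,
                                       n_observed = "observed",
                                       n_expected = "expected"))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$threshold), y = .data$count,
    fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "p-value threshold", y = "significant results",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if ("scan" %in% names(fdr)) {
    p <- p + ggplot2::facet_grid(
      ggplot2::vars(.data$level), ggplot2::vars(.data$scan))
  }
  p
}

#' P-value scatter between expression and essentiality scans
#'
#' @param p_expr,p_ess Paired p-value vectors over matched keys.
#' @return A ggplot object (-log10 scale, identity line).
#' @export
plot_modality_scatter <- function(p_expr, p_ess) {
  df <- tibble::tibble(expression = -log10(p_expr),
                       essentiality = -log10(p_ess))
  ggplot2::ggplot(df, ggplot2::aes(.data$expression, .data$essentiality)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(linetype = "dashed") +
    ggplot2::labs(x = expression(-log[10] ~ p ~ "(expression)"),
                  y = expression(-log[10] ~ p ~ "(essentiality)")) +
    ggplot2::theme_minimal()
}

#' @method autoplot synergy_scan
#' @export
autoplot.synergy_scan <- function(object, ...) {
  df <- object$results[!is.na(object$results$p_value), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$p_value)) +
    ggplot2::geom_histogram(breaks = seq(0, 1, 0.05),
                            fill = "grey40", colour = "white") +
    ggplot2::labs(x = "p-value", y = "models",
                  title = sprintf("%s / %s scan",
                                  attr(object, "analysis"),
                                  attr(object, "mode"))) +
    ggplot2::theme_minimal()
}

#' ComboScore distribution with the synergy threshold
#'
#' @param synergy_df Tibble from [score_synergy()].
#' @param threshold Synergy threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_synergy_scores <- function(synergy_df, threshold = 10) {
  ggplot2::ggplot(synergy_df, ggplot2::aes(.data$combo_score)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey40", colour = "white") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "ComboScore", y = "(pair, cell line) records") +
    ggplot2::theme_minimal()
}
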