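#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Jitter plot of enrichment across tissue-cell types
#'
#' One point per tissue-cell type at `-log10(p)` against a grouping column,
#' with a red dashed line at the Bonferroni threshold and a solid grey line
#' at the nominal threshold — the static counterpart of the usual
#' per-stratification enrichment overview.
#'
#' @param object A `csea_result` from [run_query()].
#' @param group Grouping column for the x axis (default `"organ_system"`).
#' @param p_col Which p-value to plot (default `"p_combined"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csea_result
#' @export
autoplot.csea_result <- function(object, group = "organ_system",
                                 p_col = "p_combined", ...) {
  assert_that(group %in% names(object), "grouping column not in result")
  df <- as_tibble(object)
  df$.neglog <- -log10(df[[p_col]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[group]], y = .data$.neglog,
                                   colour = .data[[group]])) +
    ggplot2::geom_jitter(width = 0.25, height = 0, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "bonferroni_threshold")),
                        colour = "red", linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(attr(object, "nominal_threshold")),
                        colour = "grey40") +
    ggplot2::labs(x = NULL, y = bquote(-log[10] * "(" * .(p_col) * ")")) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Mean Z score versus mean signature length across groups
#'
#' Visualises the signature-length bias: each point is a group (e.g. an
#' organ system) positioned by its mean signature length and its mean
#' enrichment Z score from [summarize_by_group()].
#'
#' @param summary Output of [summarize_by_group()].
#' @param group Name of the grouping column.
#' @return A ggplot object.
#' @export
plot_group_bias <- function(summary, group = names(summary)[1]) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$mean_signature_length,
                               y = .data$mean_z,
                               label = .data[[group]])) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(x = "mean signature length", y = "mean Z score") +
    ggplot2::theme_minimal()
}
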