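#' Plot explained variance per component
#'
#' @param dec a `decomposition`.
#' @param n_components how many leading components to show.
#' @return a ggplot object.
#' @export
plot_variance_explained <- function(dec, n_components = 20L) {
  df <- tidy(dec, "variance") |>
    dplyr::slice_head(n = n_components) |>
    dplyr::mutate(component = factor(.data$component,
                                     levels = .data$component))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$component,
                                   y = .data$explained_variance_fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "explained variance fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @exportS3Method ggplot2::autoplot
autoplot.decomposition <- function(object, ...) {
  plot_variance_explained(object, ...)
}

#' Plot projected scores for one component by condition
#'
#' Violin/jitter view of a component's projected scores split by
#' case/control, the primary visual check that a component separates the
#' target species' phenotype.
#'
#' @param projection a `projection` from [project_cells()].
#' @param component component name (default first).
#' @param labels optional condition labels (default: projection metadata).
#' @return a ggplot object.
#' @export
plot_component_scores <- function(projection, component = NULL,
                                  labels = NULL) {
  component <- component %||% colnames(projection$projected_scores)[1]
  labels <- labels %||% projection$cell_meta$condition
  df <- tibble::tibble(score = projection$projected_scores[, component],
                       condition = labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$score,
                                   fill = .data$condition)) +
    ggplot2::geom_violin(alpha = 0.6) +
    ggplot2::geom_boxplot(width = 0.15, outlier.shape = NA, fill = "white") +
    ggplot2::labs(x = NULL, y = paste(component, "projected score")) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.projection <- function(object, ...) {
  plot_component_scores(object, ...)
}

#' Plot an enrichment table
#'
#' Horizontal bars of normalized enrichment scores, colored by
#' significance at `alpha`.
#'
#' @param enrichment tibble from [fgsea_preranked()].
#' @param alpha adjusted-p threshold drawn in the legend.
#' @return a ggplot object.
#' @export
plot_enrichment <- function(enrichment, alpha = 0.05) {
  df <- enrichment |>
    dplyr::arrange(.data$nes) |>
    dplyr::mutate(set = factor(.data$set, levels = .data$set),
                  significant = .data$padj < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$nes, y = .data$set,
                                   fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "NES", y = NULL,
                  fill = sprintf("padj < %.2g", alpha)) +
    ggplot2::theme_minimal()
}

#' Plot a drug screen as a rho-ranked scatter
#'
#' Drugs ordered by Spearman rho; points colored by BH significance, so
#' the extreme ranks (strongest disease-like and disease-opposing
#' signatures) stand out.
#'
#' @param screen tibble from [screen_drugs()].
#' @param alpha q-value threshold.
#' @return a ggplot object.
#' @export
plot_drug_screen <- function(screen, alpha = 0.05) {
  df <- dplyr::mutate(screen, significant = .data$q_value < alpha)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$rho,
                                   color = .data$significant)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "rank (ascending rho)", y = "Spearman rho",
                  color = sprintf("q < %.2g", alpha)) +
    ggplot2::theme_minimal()
}
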