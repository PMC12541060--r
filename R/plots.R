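#' Link strength versus genomic distance
#' @param object `link_network` tibble.
#' @param ... unused.
#' @return ggplot object; reliable links highlighted.
#' @export
autoplot.link_network <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$distance / 1e3, y = .data$z,
                               color = .data$reliable)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey70",
                                           `TRUE` = "#d7301f")) +
    ggplot2::labs(x = "distance to TSS (kb)", y = "null-calibrated z",
                  color = "reliable") +
    ggplot2::theme_minimal()
}

#' One-row summary of a link network
#' @param x `link_network` tibble.
#' @param ... unused.
#' @return tibble with counts and the cutoffs used.
#' @export
glance.link_network <- function(x, ...) {
  tibble::tibble(
    n_pairs = nrow(x),
    n_reliable = sum(x$reliable),
    n_genes = length(unique(x$gene[x$reliable])),
    fdr_cut = attr(x, "fdr_cut"),
    coaccess_cut = attr(x, "coaccess_cut")
  )
}

#' Deviation z-score summary heatmap by cell type
#' @param deviations `deviation_result`.
#' @param cell_meta tibble with `barcode` and `cell_type`.
#' @param motifs optional subset of motifs to show.
#' @return ggplot tile plot of mean z per motif and cell type.
#' @export
plot_deviation_heatmap <- function(deviations, cell_meta, motifs = NULL) {
  df <- tidy.deviation_result(deviations)
  df$cell_type <- cell_meta$cell_type[match(df$cell, cell_meta$barcode)]
  if (!is.null(motifs)) df <- df[df$motif %in% motifs, ]
  agg <- df |>
    dplyr::group_by(.data$motif, .data$cell_type) |>
    dplyr::summarise(mean_z = mean(.data$z, na.rm = TRUE), .groups = "drop")
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$cell_type, y = .data$motif,
                                    fill = .data$mean_z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
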