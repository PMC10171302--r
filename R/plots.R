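#' Presence/absence heatmap
#'
#' ggplot2 heatmap of a [presence_matrix] in the style of gene-content
#' figures: presence in red, absence in black, one row per genome. When a
#' tree from [upgma()] is supplied, rows follow its [leaf_order()].
#'
#' @param object a [presence_matrix].
#' @param tree optional `anf_tree` fixing the row order.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.presence_matrix <- function(object, tree = NULL, ...) {
  long <- tidy(object)
  ord <- if (is.null(tree)) rownames(object$cells) else leaf_order(tree)
  long$genome_id <- factor(long$genome_id, levels = rev(ord))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$feature_id, y = .data$genome_id,
                                     fill = factor(.data$present))) +
    ggplot2::geom_tile(colour = "grey30", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = c(`0` = "black", `1` = "red3"),
                               name = "present") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$category_id),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' Per-genome ANF profile bar chart
#'
#' Stacked bars of gene counts per ANF category for each genome.
#'
#' @param profiles_tbl output of [profiles()].
#' @return a ggplot object.
#' @export
plot_profiles <- function(profiles_tbl) {
  long <- profiles_tbl |>
    dplyr::select(-"total_genes", -"categories_covered") |>
    tidyr::pivot_longer(-"genome_id", names_to = "category_id",
                        values_to = "n_genes")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$genome_id, y = .data$n_genes,
                                     fill = .data$category_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "ANF genes", fill = "category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1,
                                                       vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
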