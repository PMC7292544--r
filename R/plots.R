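#' Heatmap of a clustered z-score matrix
#'
#' Tile heatmap of gene z-scores across conditions with rows and columns in
#' dendrogram order, faceted by gene cluster and condition group.
#'
#' @param object A `quantcap_clusters` from [cluster_profiles()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quantcap_clusters
#' @export
autoplot.quantcap_clusters <- function(object, ...) {
  z_long <- tidyr::pivot_longer(object$z, -"gene_id",
                                names_to = "condition", values_to = "z")
  gene_order <- object$gene_tree$labels[object$gene_tree$order]
  cond_order <- object$condition_tree$labels[object$condition_tree$order]
  z_long <- z_long |>
    dplyr::left_join(object$gene_labels, by = "gene_id") |>
    dplyr::left_join(object$condition_labels, by = "condition") |>
    dplyr::mutate(
      gene_id = factor(.data$gene_id, levels = gene_order),
      condition = factor(.data$condition, levels = cond_order)
    )
  ggplot2::ggplot(z_long, ggplot2::aes(x = .data$condition, y = .data$gene_id,
                                       fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$cluster),
                        cols = ggplot2::vars(.data$group),
                        scales = "free", space = "free") +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "condition", y = "gene", fill = "z") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}

#' Correlation heatmap
#'
#' @param object A `quantcap_cor` from [correlate_columns()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot quantcap_cor
#' @export
autoplot.quantcap_cor <- function(object, ...) {
  long <- tidy(object)
  items <- object$item
  long <- dplyr::mutate(long,
    item1 = factor(.data$item1, levels = items),
    item2 = factor(.data$item2, levels = items)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$item1, y = .data$item2,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0("r (", attr(object, "method"), ")")) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5,
                                                       hjust = 1))
}

#' Bait tiling plot
#'
#' Shows each gene's designed probes as stacked segments along the capture
#' window, coloured by filter status.
#'
#' @param object A `bait_library` from [design_baits()].
#' @param genes Optional subset of gene IDs to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bait_library
#' @export
autoplot.bait_library <- function(object, genes = NULL, ...) {
  baits <- object$baits
  if (!is.null(genes)) baits <- dplyr::filter(baits, .data$source_gene %in% genes)
  baits <- baits |>
    dplyr::group_by(.data$source_gene) |>
    dplyr::mutate(row = (dplyr::row_number() - 1L) %% 3L) |>
    dplyr::ungroup()
  ggplot2::ggplot(baits) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start, xend = .data$end,
                                       y = .data$row, yend = .data$row,
                                       colour = .data$status),
                          linewidth = 2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$source_gene), scales = "free_x") +
    ggplot2::labs(x = "genomic position (bp)", y = NULL, colour = "status") +
    ggplot2::scale_y_continuous(breaks = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}

#' Scatter plot of two condition profiles
#'
#' Paired per-gene comparison of two conditions' log-ratio profiles with
#' the identity line and the r-squared annotation.
#'
#' @param profile A `condition_profile` (or any wide gene x condition
#'   tibble).
#' @param cond_x,cond_y Condition column names.
#' @param method Correlation method.
#' @return A ggplot object.
#' @export
plot_condition_scatter <- function(profile, cond_x, cond_y,
                                   method = c("pearson", "spearman")) {
  cp <- cor_pair(profile, cond_x, cond_y, method = method)
  ggplot2::ggplot(cp$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60",
                         linetype = 2) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                      label = sprintf("r^2 == %.2f", cp$r_squared),
                      parse = TRUE) +
    ggplot2::labs(x = paste0("log2 ratio (", cond_x, ")"),
                  y = paste0("log2 ratio (", cond_y, ")")) +
    ggplot2::theme_minimal(base_size = 10)
}
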