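# ggplot2 visualisations for the main result types.

#' MA plot of a pairwise DE result
#'
#' Log2 fold change against average log abundance, DE calls highlighted.
#'
#' @param object A `tx_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tx_de <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$log_cpm, y = .data$log_fc,
                                    colour = .data$is_de)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick"),
                                 name = "DE") +
    ggplot2::geom_hline(yintercept = c(-object$lfc_cutoff,
                                       object$lfc_cutoff),
                        linetype = "dashed", colour = "grey30") +
    ggplot2::labs(x = "average log2 CPM", y = "log2 fold change",
                  title = paste(object$contrast, collapse = " vs ")) +
    ggplot2::theme_minimal()
}

#' MDS plot of library relationships
#'
#' @param object A `tx_mds` tibble from [mds_coordinates()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tx_mds <- function(object, ...) {
  has_design <- all(c("photoperiod", "bloodmeal") %in% names(object))
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (has_design) {
    p <- p + ggplot2::geom_text(ggplot2::aes(
      label = paste0(.data$photoperiod, ".", .data$bloodmeal),
      colour = .data$photoperiod))
  } else {
    p <- p + ggplot2::geom_text(ggplot2::aes(label = .data$library_id))
  }
  p + ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Enrichment dot plot
#'
#' @param object A `tx_enrichment` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.tx_enrichment <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  tab$pathway_id <- stats::reorder(tab$pathway_id, -log10(tab$fdr))
  ggplot2::ggplot(tab, ggplot2::aes(x = -log10(.data$fdr),
                                    y = .data$pathway_id,
                                    size = .data$n_de_in_pathway,
                                    colour = .data$enriched)) +
    ggplot2::geom_point() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "-log10 FDR", y = NULL, size = "DE genes") +
    ggplot2::theme_minimal()
}

#' Z-score heat map of DE genes in a pathway
#'
#' @param z Result of [zscore_matrix()].
#' @return A ggplot of the standardized matrix in clustered order.
#' @export
plot_zscore_heatmap <- function(z) {
  m <- z$z[z$row_order, z$col_order, drop = FALSE]
  df <- tibble::tibble(
    gene = factor(rep(rownames(m), ncol(m)), levels = rev(rownames(m))),
    library = factor(rep(colnames(m), each = nrow(m)), levels = colnames(m)),
    value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$library, y = .data$gene,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", name = "Z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
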