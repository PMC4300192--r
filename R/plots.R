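#' Entropy distribution with the filter cut
#'
#' Histogram of per-gene entropy; when a filter fraction is given, genes
#' above the implied cut (the removed, most-uniform genes) are shaded
#' separately.
#'
#' @param report Entropy report from [gene_entropy()].
#' @param fraction Optional filter fraction used to shade removed genes.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_entropy <- function(report, fraction = NULL, bins = 40L) {
  stopifnot(is.data.frame(report), "entropy" %in% names(report))
  df <- tibble::as_tibble(report)
  if (!is.null(fraction) && fraction > 0) {
    df$status <- ifelse(entropy_retained(df$entropy, fraction),
                        "retained", "removed")
  } else if (!all(is.na(df$retained))) {
    df$status <- ifelse(df$retained, "retained", "removed")
  } else {
    df$status <- "retained"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$entropy, fill = .data$status)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::scale_fill_manual(
      values = c(retained = "grey35", removed = "firebrick")) +
    ggplot2::labs(x = "gene entropy (nats)", y = "genes", fill = NULL,
                  title = "Entropy filter: uniform genes sit at the top") +
    ggplot2::theme_minimal()
}

#' Topological-overlap similarity heatmap in dendrogram order
#'
#' Rows and columns are permuted to the clustering leaf order so modules
#' appear as hot blocks along the diagonal.
#'
#' @param sim A `topo_similarity`.
#' @param assign Matching `module_assignment` (supplies the leaf order).
#' @return A ggplot object.
#' @export
plot_similarity_heatmap <- function(sim, assign) {
  ord <- order_for_heatmap(sim, assign)
  s <- sim$s[ord, ord, drop = FALSE]
  k <- nrow(s)
  df <- tibble::tibble(row = rep(seq_len(k), times = k),
                       col = rep(seq_len(k), each = k),
                       similarity = as.vector(s))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$similarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "s",
                  title = "Topological-overlap similarity (dendrogram order)") +
    ggplot2::theme_minimal()
}

#' Module size bar chart
#'
#' @param assign A `module_assignment` (or any tibble with `module_label`).
#' @return A ggplot object.
#' @export
plot_module_sizes <- function(assign) {
  stopifnot(is.data.frame(assign), "module_label" %in% names(assign))
  tab <- table(assign$module_label)
  df <- tibble::tibble(module = names(tab), genes = as.integer(tab))
  num <- suppressWarnings(as.integer(df$module))
  df$module <- factor(df$module,
                      levels = c(as.character(sort(num[!is.na(num)])),
                                 intersect(c("unassigned", "unconnected"),
                                           df$module)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$genes)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "module", y = "genes") +
    ggplot2::theme_minimal()
}
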