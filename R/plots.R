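# ggplot2 graphics for the main result types.

#' @export
autoplot.fnmf_fit <- function(object, ...) {
  df <- tibble(iteration = seq_along(object$objective),
               error = object$objective)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "Frobenius reconstruction error",
                  title = sprintf("FNMF objective (k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' Heatmap of region-link significance
#'
#' @param links output of [region_significance()] (rows for one or several
#'   gene sets).
#' @param alpha significance level drawn as a contour in the fill scale.
#' @return A ggplot object: gene sets by regions, filled by
#'   -log10(adjusted p), significant cells outlined.
#' @export
plot_region_significance <- function(links, alpha = 0.05) {
  df <- mutate(links, neglogp = -log10(.data$adjusted_p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$gene_set_id,
                                   fill = .data$neglogp)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = filter(df, .data$significant),
                       colour = "black", linewidth = 0.6, fill = NA) +
    ggplot2::scale_fill_viridis_c(name = "-log10 adj. p") +
    ggplot2::labs(x = "brain region", y = "gene set") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Bar chart of regulator-signature module sizes
#'
#' @param modules a `module_assignment`.
#' @return A ggplot object.
#' @export
plot_module_sizes <- function(modules) {
  df <- module_sizes(modules)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$module, y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = "module", y = "genes",
                  title = "Regulator-signature modules") +
    ggplot2::theme_minimal()
}

#' Degree distribution of a network
#'
#' @param net `omic_network`, `tcmin`, or igraph.
#' @return A ggplot object (log-log degree histogram).
#' @export
plot_degree_distribution <- function(net) {
  g <- as_igraph(net)
  df <- count(tibble(degree = igraph::degree(g)), .data$degree)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "nodes") +
    ggplot2::theme_minimal()
}
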