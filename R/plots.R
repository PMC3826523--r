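#' Plot a gene map of one or more genomes
#'
#' Chromosomes as horizontal lines, loci as points colored by family, one
#' facet per species.
#'
#' @param table A locus tibble.
#' @param species Optional subset of species.
#' @return A ggplot object.
#' @export
plot_locus_map <- function(table, species = NULL) {
  tbl <- as_locus_table(table)
  if (!is.null(species)) tbl <- dplyr::filter(tbl, .data$species %in% !!species)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$start / 1e6,
                                    y = .data$chromosome)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$chromosome),
                       color = "grey80", linewidth = 2) +
    ggplot2::geom_point(ggplot2::aes(color = .data$family), size = 2) +
    ggplot2::facet_wrap(~species, scales = "free_y") +
    ggplot2::labs(x = "position (Mb)", y = NULL, color = "family") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.paralogon_groups <- function(object, ...) {
  g <- attr(object, "graph")
  lay <- igraph::layout_in_circle(g)
  nodes <- tibble::tibble(name = igraph::V(g)$name,
                          x = lay[, 1], y = lay[, 2])
  nodes$group <- factor(object$group[match(nodes$name, object$block_id)])
  el <- igraph::as_data_frame(g, what = "edges")
  edges <- NULL
  if (nrow(el)) {
    edges <- dplyr::mutate(el,
                           x = nodes$x[match(.data$from, nodes$name)],
                           y = nodes$y[match(.data$from, nodes$name)],
                           xend = nodes$x[match(.data$to, nodes$name)],
                           yend = nodes$y[match(.data$to, nodes$name)])
  }
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (!is.null(edges)) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      color = "grey60")
  }
  p + ggplot2::geom_point(ggplot2::aes(color = .data$group), size = 5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$name), vjust = -1.2,
                       size = 3) +
    ggplot2::scale_linewidth(range = c(0.3, 2)) +
    ggplot2::coord_equal(clip = "off") +
    ggplot2::theme_void() +
    ggplot2::labs(color = "paralogon", linewidth = "shared families")
}

#' @export
autoplot.dollo_recon <- function(object, ...) {
  ggplot2::ggplot(object$content,
                  ggplot2::aes(x = .data$node, y = .data$family,
                               fill = .data$n)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "ancestor / node", y = "family",
                  fill = "lineages") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.dup_calls <- function(object, ...) {
  counts <- dplyr::count(tibble::as_tibble(object), .data$window)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$window, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "time-window", y = "duplication nodes") +
    ggplot2::theme_minimal()
}
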