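# ggplot2 displays for the main result types.

#' Plot a repeat landscape
#'
#' Stacked masked-bp histogram by Kimura divergence bin, one fill per family
#' — young, homogeneous families peak near zero divergence.
#'
#' @param x A `satkit_landscape` tibble from [landscape()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.satkit_landscape <- function(x, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = .data$bin_low + 0.5, y = .data$pct_genome,
                                  fill = .data$family)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "Kimura divergence to consensus (%)",
                  y = "Genome proportion (%)", fill = "Family") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.satkit_landscape
#' @export
plot_landscape <- function(x, ...) autoplot.satkit_landscape(x, ...)

#' Plot a subfamily co-occurrence matrix
#'
#' Heatmap of the fraction of scaffolds shared by each subfamily pair.
#'
#' @param x A `satkit_cooccurrence` matrix from [cooccurrence()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.satkit_cooccurrence <- function(x, ...) {
  m <- unclass(x)
  df <- as_tibble(as.table(m), .name_repair = ~ c("a", "b", "shared"))
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$shared)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = NULL, y = NULL, fill = "Shared\nfraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @rdname autoplot.satkit_cooccurrence
#' @export
plot_cooccurrence <- function(x, ...) autoplot.satkit_cooccurrence(x, ...)

#' Plot a minimum spanning network
#'
#' Nodes sized by abundance and coloured by monomer length; edges labelled
#' with mutational steps.
#'
#' @param x A `satkit_msn` from [build_msn()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.satkit_msn <- function(x, ...) {
  set.seed(1)
  lay <- igraph::layout_with_fr(x$graph)
  nodes <- mutate(x$nodes, x = lay[, 1], y = lay[, 2])
  edges <- x$edges |>
    left_join(select(nodes, "name", xa = "x", ya = "y"), by = c(from = "name")) |>
    left_join(select(nodes, "name", xb = "x", yb = "y"), by = c(to = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$xa, y = .data$ya,
                                       xend = .data$xb, yend = .data$yb),
                          colour = "grey60") +
    ggplot2::geom_text(data = edges,
                       ggplot2::aes(x = (.data$xa + .data$xb) / 2,
                                    y = (.data$ya + .data$yb) / 2,
                                    label = paste0("(", .data$steps, ")")),
                       size = 3) +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(.data$x, .data$y, size = .data$weight,
                                     colour = .data$length)) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       vjust = -1.2, size = 3) +
    ggplot2::scale_size_area(max_size = 12) +
    ggplot2::labs(size = "Abundance", colour = "Monomer (bp)") +
    ggplot2::theme_void()
}

#' @rdname autoplot.satkit_msn
#' @export
plot_msn <- function(x, ...) autoplot.satkit_msn(x, ...)

#' Plot tissue expression patterns
#'
#' Per-family grouped bars of tissue-group mean CPM, faceted by assigned
#' pattern.
#'
#' @param patterns Output of [expression_patterns()] (retained rows used).
#' @return A ggplot object.
#' @export
plot_expression_patterns <- function(patterns) {
  df <- patterns |>
    filter(.data$retained) |>
    tidyr::pivot_longer(c("antenna", "ovary", "testis"),
                        names_to = "tissue", values_to = "cpm")
  ggplot2::ggplot(df, ggplot2::aes(.data$family, .data$cpm, fill = .data$tissue)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$pattern), scales = "free") +
    ggplot2::labs(x = NULL, y = "Mean CPM", fill = "Tissue") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
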