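# broom-style tidiers for satkit result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy satkit objects
#'
#' `tidy()` returns the per-element table of a result object (arrays for a
#' simulated genome, edges for a network, families for a satellitome);
#' `glance()` returns a one-row summary.
#'
#' @param x A satkit result object.
#' @param ... Unused.
#' @return A tibble.
#' @name satkit-tidiers
NULL

#' @rdname satkit-tidiers
#' @export
tidy.satkit_genome <- function(x, ...) x$arrays

#' @rdname satkit-tidiers
#' @export
glance.satkit_genome <- function(x, ...) {
  tibble(genome_length = x$genome_length, n_scaffolds = nrow(x$genome),
         n_arrays = nrow(x$arrays), n_families = nrow(x$families),
         satellite_fraction = sum(x$arrays$end - x$arrays$start) / x$genome_length)
}

#' @rdname satkit-tidiers
#' @export
tidy.satkit_satellitome <- function(x, ...) select(x$families, -"consensus")

#' @rdname satkit-tidiers
#' @export
glance.satkit_satellitome <- function(x, ...) {
  tibble(n_families = nrow(x$families),
         n_clusters = nrow(x$clusters),
         n_tandem_clusters = sum(x$clusters$tandem, na.rm = TRUE),
         total_proportion_pct = sum(x$families$proportion_pct),
         masked_bp = sum(x$hits$end - x$hits$start),
         total_bp = x$total_bp)
}

#' @rdname satkit-tidiers
#' @export
tidy.satkit_msn <- function(x, ...) x$edges

#' @rdname satkit-tidiers
#' @export
glance.satkit_msn <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         total_steps = sum(x$edges$steps),
         connected = igraph::is_connected(x$graph))
}

#' @rdname satkit-tidiers
#' @export
tidy.satkit_correlation <- function(x, ...) {
  tibble(estimate = x$r_s, p.value = x$p_value, n = x$n, method = x$method)
}

#' @rdname satkit-tidiers
#' @export
glance.satkit_correlation <- tidy.satkit_correlation
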