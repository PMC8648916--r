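#' Tidy a co-occurrence network
#'
#' @param x A `cooccur_network`.
#' @param ... Unused.
#' @return The edge tibble (one row per edge).
#' @method tidy cooccur_network
#' @export
tidy.cooccur_network <- function(x, ...) {
  tibble::as_tibble(x$edges)
}

#' One-row summary of a co-occurrence network
#'
#' @param x A `cooccur_network`.
#' @param ... Unused.
#' @return A tibble with node, edge, sign and module counts.
#' @method glance cooccur_network
#' @export
glance.cooccur_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_positive = sum(x$edges$sign == "+"),
    n_negative = sum(x$edges$sign == "-"),
    n_modules = length(unique(stats::na.omit(x$nodes$module))),
    n_unassigned = sum(is.na(x$nodes$module)))
}

#' Tidy a sequential PERMANOVA fit
#'
#' @param x A `permanova_fit`.
#' @param ... Unused.
#' @return The per-term table, including residual and total rows.
#' @method tidy permanova_fit
#' @export
tidy.permanova_fit <- function(x, ...) {
  x$table
}

#' One-row summary of a sequential PERMANOVA fit
#'
#' @param x A `permanova_fit`.
#' @param ... Unused.
#' @return A tibble with the sample count, permutations and the first
#'   term's statistics.
#' @method glance permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble::tibble(n_samples = x$n_samples,
                 permutations = x$permutations,
                 n_terms = length(x$terms))
}

#' Tidy a PCoA ordination
#'
#' @param x A `pcoa_ord`.
#' @param ... Unused.
#' @return The sample coordinate tibble.
#' @method tidy pcoa_ord
#' @export
tidy.pcoa_ord <- function(x, ...) {
  x$coordinates
}

#' One-row summary of a PCoA ordination
#'
#' @param x A `pcoa_ord`.
#' @param ... Unused.
#' @return A tibble with axis count and variance explained by the first
#'   two axes.
#' @method glance pcoa_ord
#' @export
glance.pcoa_ord <- function(x, ...) {
  k <- min(2, length(x$prop_explained))
  tibble::tibble(n_axes = length(x$eigenvalues),
                 prop_axis1 = x$prop_explained[1],
                 prop_first_two = sum(x$prop_explained[seq_len(k)]))
}
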