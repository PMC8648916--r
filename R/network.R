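#' Select network edges from association results
#'
#' Either the `k` most significant pairs (smallest q, ties broken by
#' larger |z| then lexicographic pair) or all pairs with `q <= q_max`.
#' The effective q-value of the last included edge is attached as the
#' `effective_q` attribute. A `sign` column (`"+"`/`"-"`, the sign of z)
#' is added.
#'
#' @param results An `association_results` tibble from [reboot()].
#' @param mode `"top_k"` (default) or `"q_threshold"`.
#' @param k Number of edges kept in `top_k` mode (default 500).
#' @param q_max Threshold in `q_threshold` mode (default 0.05).
#' @return A tibble of edges with attribute `effective_q`.
#' @export
select_edges <- function(results, mode = c("top_k", "q_threshold"),
                         k = 500, q_max = 0.05) {
  mode <- match.arg(mode)
  res <- dplyr::filter(results, is.finite(.data$q))
  res <- dplyr::mutate(res, sign = ifelse(.data$z > 0, "+", "-"))
  out <- if (mode == "top_k") {
    if (k > nrow(res)) {
      warning("requested ", k, " edges but only ", nrow(res),
              " associations available; keeping all", call. = FALSE)
      k <- nrow(res)
    }
    ord <- order(res$q, -abs(res$z), res$otu_a, res$otu_b)
    res[ord[seq_len(k)], , drop = FALSE]
  } else {
    dplyr::filter(res, .data$q <= q_max)
  }
  attr(out, "effective_q") <- if (nrow(out)) max(out$q) else NA_real_
  out
}

#' Build a signed co-occurrence network
#'
#' Nodes are the OTUs incident to at least one selected edge; edges carry
#' the association sign (sign of z), similarity, z, p and q. Mean
#' abundances (for node sizing) and taxonomy labels are attached when the
#' corresponding tables are supplied. Self-edges are never created since
#' associations are defined over unordered distinct pairs.
#'
#' @param edges Edge tibble from [select_edges()].
#' @param abundance Optional `abund_tbl`; per-OTU mean abundance across
#'   samples is stored as `mean_abundance`.
#' @param taxonomy Optional taxonomy tibble keyed by `otu_id`.
#' @return An object of class `cooccur_network`: a list with tibbles
#'   `nodes` (`otu_id`, `mean_abundance`, taxonomy ranks, `module`) and
#'   `edges`.
#' @export
build_network <- function(edges, abundance = NULL, taxonomy = NULL) {
  stopifnot(all(c("otu_a", "otu_b", "z", "q") %in% names(edges)))
  if (any(edges$otu_a == edges$otu_b)) {
    stop("self-edges are not allowed", call. = FALSE)
  }
  if (!"sign" %in% names(edges)) {
    edges <- dplyr::mutate(edges, sign = ifelse(.data$z > 0, "+", "-"))
  }
  nodes <- tibble::tibble(otu_id = sort(unique(c(edges$otu_a, edges$otu_b))))
  if (!is.null(abundance)) {
    m <- abund_matrix(abundance)
    nodes$mean_abundance <- colMeans(m)[nodes$otu_id]
  }
  if (!is.null(taxonomy)) {
    nodes <- dplyr::left_join(nodes, taxonomy, by = "otu_id")
  }
  nodes$module <- NA_integer_
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges)),
            class = "cooccur_network")
}

#' @export
print.cooccur_network <- function(x, ...) {
  n_pos <- sum(x$edges$sign == "+")
  n_mod <- length(unique(stats::na.omit(x$nodes$module)))
  cat(sprintf(paste0("# Co-occurrence network: %d nodes, %d edges ",
                     "(%d positive, %d negative), %d modules\n"),
              nrow(x$nodes), nrow(x$edges), n_pos,
              nrow(x$edges) - n_pos, n_mod))
  invisible(x)
}

# igraph of the positive-edge subgraph; unweighted unless weighted = TRUE
positive_subgraph <- function(net, weighted = FALSE) {
  pos <- dplyr::filter(net$edges, .data$sign == "+")
  g <- igraph::graph_from_data_frame(
    pos[c("otu_a", "otu_b")], directed = FALSE,
    vertices = unique(c(pos$otu_a, pos$otu_b)))
  if (weighted) igraph::E(g)$weight <- abs(pos$z)
  g
}

#' Detect modules with the walktrap algorithm
#'
#' Random-walk community detection (walk length `steps`, default 20) on
#' the subgraph of positive edges only, unweighted by default. Nodes with
#' only negative edges do not appear in that subgraph and are left
#' unassigned (`NA` module). Module ids are relabelled in decreasing
#' order of node count, so module 1 is always the largest.
#'
#' @param net A `cooccur_network`.
#' @param steps Walktrap walk length.
#' @param weighted If `TRUE`, walks are weighted by |z| of the edges.
#' @return The network with the `module` column of `nodes` filled in.
#' @export
detect_modules <- function(net, steps = 20, weighted = FALSE) {
  stopifnot(inherits(net, "cooccur_network"))
  if (nrow(net$edges) == 0) stop("network has no edges", call. = FALSE)
  g <- positive_subgraph(net, weighted)
  if (igraph::vcount(g) == 0) {
    warning("positive-edge subgraph is empty; all nodes unassigned",
            call. = FALSE)
    net$nodes$module <- NA_integer_
    return(net)
  }
  wt <- igraph::cluster_walktrap(g, steps = steps)
  memb <- igraph::membership(wt)
  # relabel in decreasing order of module size (ties by original label)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  memb <- setNames(as.integer(relabel[as.character(memb)]), names(memb))
  net$nodes$module <- unname(memb[net$nodes$otu_id])
  net
}

#' Concordance between modules and a taxonomy rank
#'
#' Adjusted Rand index between the detected module partition and the
#' partition induced by a taxonomy rank, over OTUs that are both assigned
#' to a module and labelled at that rank. Quantifies how phylogenetically
#' clustered the modules are.
#'
#' @param net A `cooccur_network` with modules detected, or a tibble with
#'   columns `otu_id`, `module`.
#' @param taxonomy Taxonomy tibble keyed by `otu_id`.
#' @param rank Name of the taxonomy column to compare against.
#' @return Adjusted Rand index.
#' @export
module_taxonomy_concordance <- function(net, taxonomy, rank) {
  nodes <- if (inherits(net, "cooccur_network")) net$nodes else net
  if (!rank %in% names(taxonomy)) {
    stop("rank '", rank, "' not present in taxonomy", call. = FALSE)
  }
  joined <- dplyr::inner_join(
    dplyr::filter(nodes, !is.na(.data$module)),
    dplyr::filter(taxonomy, !is.na(.data[[rank]])),
    by = "otu_id")
  if (nrow(joined) < 2) {
    stop("fewer than 2 OTUs with both module and '", rank, "' label",
         call. = FALSE)
  }
  mclust::adjustedRandIndex(joined$module, joined[[rank]])
}

as_igraph <- function(net) {
  v <- as.data.frame(net$nodes)
  v$module <- ifelse(is.na(v$module), "", as.character(v$module))
  names(v)[1] <- "name"
  igraph::graph_from_data_frame(as.data.frame(net$edges),
                                directed = FALSE, vertices = v)
}

#' Export a network to GraphML and an edge-list TSV
#'
#' The GraphML file carries node attributes (module — empty string for
#' unassigned nodes — plus mean abundance and taxonomy when present) and
#' edge attributes (sign, similarity, z, p, q). The TSV has columns
#' `otu_a`, `otu_b`, `similarity`, `z`, `p`, `q`, `sign`.
#'
#' @param net A `cooccur_network`.
#' @param path_graphml Output GraphML path.
#' @param path_edges Output TSV path.
#' @return Invisibly, a list of the two paths.
#' @export
write_network <- function(net, path_graphml, path_edges) {
  stopifnot(inherits(net, "cooccur_network"))
  igraph::write_graph(as_igraph(net), path_graphml, format = "graphml")
  readr::write_tsv(net$edges[c("otu_a", "otu_b", "similarity",
                               "z", "p", "q", "sign")], path_edges)
  invisible(list(graphml = path_graphml, edges = path_edges))
}

#' Read a network edge list written by [write_network()]
#'
#' @param path TSV path.
#' @return An edge tibble.
#' @export
read_network_edges <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    otu_a = readr::col_character(), otu_b = readr::col_character(),
    sign = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
}
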