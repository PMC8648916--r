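#' End-to-end co-occurrence network inference
#'
#' Chains the standard stages: relative abundances, max-abundance
#' filtering, optional absolute scaling, errthresh prevalence exclusion,
#' ReBoot association testing, edge selection and walktrap module
#' detection.
#'
#' @param counts An `abund_tbl` of kind `"counts"`.
#' @param densities Per-sample density tibble; required when
#'   `abundance = "absolute"`.
#' @param filter_level Max-abundance filter level or threshold
#'   (see [filter_by_max_abundance()]).
#' @param abundance `"relative"` (default) or `"absolute"`.
#' @param measure,s,iterations,variant Passed to [reboot()].
#' @param edge_mode,k,q_max Passed to [select_edges()].
#' @param steps Walktrap walk length.
#' @param taxonomy Optional taxonomy tibble attached to nodes.
#' @param seed Optional seed making the whole run reproducible.
#' @return A list with `network` (modules detected), `associations`,
#'   `edges`, `filter_report` and `errthresh_report`.
#' @export
infer_cooccurrence_network <- function(counts, densities = NULL,
                                       filter_level = "low",
                                       abundance = c("relative", "absolute"),
                                       measure = "spearman", s = "low",
                                       iterations = 1000,
                                       variant = "permutation",
                                       edge_mode = "top_k", k = 500,
                                       q_max = 0.05, steps = 20,
                                       taxonomy = NULL, seed = NULL) {
  abundance <- match.arg(abundance)
  rel <- to_relative(counts)
  filt <- filter_by_max_abundance(rel, filter_level)
  working <- filt$table
  if (abundance == "absolute") {
    if (is.null(densities)) {
      stop("absolute abundances require a density table", call. = FALSE)
    }
    working <- to_absolute(working, densities)
  }
  errth <- errthresh_filter(working)
  assoc <- reboot(errth$table, measure = measure, s = s,
                  iterations = iterations,
                  renormalize = if (abundance == "absolute") FALSE else NULL,
                  residual_pool = errth$report$residual_pool,
                  variant = variant, seed = seed)
  edges <- select_edges(assoc, mode = edge_mode, k = k, q_max = q_max)
  net <- build_network(edges, abundance = working, taxonomy = taxonomy)
  net <- detect_modules(net, steps = steps)
  list(network = net, associations = assoc, edges = edges,
       filter_report = filt$report, errthresh_report = errth$report)
}
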