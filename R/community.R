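#' Bray-Curtis distances between samples
#'
#' `d(a, b) = sum|x_a - x_b| / sum(x_a + x_b)` over OTUs; symmetric, zero
#' diagonal, values in \[0, 1\].
#'
#' @param x An `abund_tbl` with no all-zero sample.
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(x) {
  stopifnot(inherits(x, "abund_tbl"))
  m <- abund_matrix(x)
  zero <- which(rowSums(m) == 0)
  if (length(zero)) {
    stop("all-zero sample: ", rownames(m)[zero[1]], call. = FALSE)
  }
  vegan::vegdist(m, method = "bray")
}

#' Spearman dissimilarity between samples
#'
#' `d(a, b) = 1 - spearman(profile_a, profile_b)` where profiles are the
#' per-sample OTU abundance vectors; diagonal 0, range \[0, 2\]. Invariant
#' under any common strictly increasing transform of the values. A
#' constant sample profile has no defined correlation; its entries are
#' `NA` and a warning is raised.
#'
#' @param x An `abund_tbl` with at least 2 OTUs.
#' @return A `dist`-like object labelled by sample id.
#' @export
spearman_dissimilarity <- function(x) {
  stopifnot(inherits(x, "abund_tbl"))
  m <- abund_matrix(x)
  if (ncol(m) < 2) stop("need at least 2 OTUs", call. = FALSE)
  cc <- suppressWarnings(cor(t(m), method = "spearman"))
  if (anyNA(cc)) warning("constant sample profile: dissimilarity undefined",
                         call. = FALSE)
  d <- 1 - cc
  diag(d) <- 0
  stats::as.dist(d)
}

#' Principal coordinates analysis (classical scaling)
#'
#' Double-centres the squared distance matrix and eigendecomposes it.
#' Axes with negative eigenvalues (from non-Euclidean distances) are
#' dropped with a warning and excluded from the proportion-explained
#' denominator; no Cailliez/Lingoes correction is applied.
#'
#' @param d A `dist` object or square symmetric matrix with zero diagonal.
#' @return An object of class `pcoa_ord`: list with `coordinates` (tibble
#'   `sample_id`, `Axis1`, `Axis2`, ...), `eigenvalues` (descending, the
#'   positive ones) and `prop_explained`.
#' @export
pcoa_ordination <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) {
      stop("distance matrix must be symmetric", call. = FALSE)
    }
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  tol <- 1e-8 * max(abs(eig))
  if (any(eig < -tol)) {
    warning("dropping ", sum(eig < -tol),
            " axes with negative eigenvalues", call. = FALSE)
  }
  pos <- which(eig > tol)
  coords <- fit$points[, pos, drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(list(
    coordinates = dplyr::bind_cols(
      tibble::tibble(sample_id = labels(d)),
      tibble::as_tibble(coords)),
    eigenvalues = eig[pos],
    prop_explained = eig[pos] / sum(eig[pos])),
    class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  cat(sprintf("# PCoA ordination: %d samples, %d axes (%.1f%% on axes 1-2)\n",
              nrow(x$coordinates), length(x$eigenvalues),
              100 * sum(x$prop_explained[seq_len(min(2,
                length(x$prop_explained)))])))
  invisible(x)
}

#' Sequential PERMANOVA on a dissimilarity matrix
#'
#' Sequential (Type I) permutational multivariate analysis of variance:
#' terms are added in the given order, sums of squares come from the
#' Gower-centred matrix and each term's pseudo-F is tested against free
#' permutations of the samples, `p = (#\{F_perm >= F_obs\} + 1) /
#' (permutations + 1)`. Computed via [vegan::adonis2()] with
#' `by = "terms"`. The study design motivating this function compares the
#' selection group (first term) against the current selection regime
#' (second term) on samples from day 28 (just before the crossover) and
#' day 50 (the end point); pass `days = c(28, 50)` for that restriction.
#'
#' @param d A `dist` object over samples.
#' @param metadata Metadata tibble containing `sample_id` and the term
#'   columns; every sample of `d` must be present.
#' @param terms Character vector of metadata columns, in testing order.
#' @param permutations Number of permutations (default 9999; increase for
#'   publication-grade p-values).
#' @param days Optional vector of days to restrict the samples to.
#' @return An object of class `permanova_fit` with a per-term table
#'   (`df`, `sum_sq`, `r_squared`, `pseudo_f`, `p_value`) plus residual
#'   and total rows.
#' @export
permanova_sequential <- function(d, metadata,
                                 terms = c("selection_group",
                                           "current_regime"),
                                 permutations = 9999, days = NULL) {
  stopifnot(inherits(d, "dist"))
  ids <- labels(d)
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    stop("metadata missing for some samples in the distance matrix",
         call. = FALSE)
  }
  if (!is.null(days)) {
    keep <- meta$day %in% days
    if (!any(keep)) stop("no samples on the requested days", call. = FALSE)
    d <- stats::as.dist(as.matrix(d)[keep, keep])
    meta <- meta[keep, , drop = FALSE]
  }
  missing <- setdiff(terms, names(meta))
  if (length(missing)) {
    stop("metadata missing term columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (t in terms) {
    if (length(unique(meta[[t]])) < 2) {
      stop("factor '", t, "' has fewer than 2 levels", call. = FALSE)
    }
  }
  df <- as.data.frame(meta)
  frm <- stats::as.formula(paste("d ~", paste(terms, collapse = " + ")))
  fit <- vegan::adonis2(frm, data = df, permutations = permutations,
                        by = "terms")
  tab <- tibble::tibble(
    term = rownames(fit),
    df = fit$Df,
    sum_sq = fit$SumOfSqs,
    r_squared = fit$R2,
    pseudo_f = fit$F,
    p_value = fit$`Pr(>F)`)
  structure(list(table = tab, permutations = permutations, terms = terms,
                 n_samples = nrow(df)),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("# Sequential PERMANOVA (%d samples, %d permutations)\n",
              x$n_samples, x$permutations))
  print(as.data.frame(x$table), digits = 4)
  invisible(x)
}
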