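#' Pairwise similarity of two abundance vectors
#'
#' Pearson or Spearman correlation in \[-1, 1\]. Spearman uses average
#' ranks for ties. A vector that is constant (or constant after the rank
#' transform) has no defined correlation; the value is returned as `NA`
#' and such pairs are skipped downstream.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param measure `"spearman"` (default) or `"pearson"`.
#' @return A real in \[-1, 1\], or `NA` if undefined.
#' @export
similarity <- function(x, y, measure = c("spearman", "pearson")) {
  measure <- match.arg(measure)
  if (length(x) != length(y)) stop("vectors must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  suppressWarnings(cor(x, y, method = measure))
}

#' Noise-injected similarity
#'
#' Evaluates the similarity measure after adding i.i.d. Gaussian noise
#' `N(0, gamma^2)` independently to every component of both vectors:
#' `f*(x, y) = f(x + eps_x, y + eps_y)`. The noise breaks patterns of
#' double zeros that would otherwise create spurious correlations between
#' rare OTUs. Fresh noise is drawn on every invocation; with `gamma = 0`
#' the result is bit-for-bit identical to [similarity()].
#'
#' @inheritParams similarity
#' @param gamma Noise standard deviation (>= 0); see [noise_gamma()].
#' @return A real in \[-1, 1\], or `NA` if undefined.
#' @export
noisy_similarity <- function(x, y, measure = c("spearman", "pearson"),
                             gamma = 0) {
  measure <- match.arg(measure)
  stopifnot(gamma >= 0)
  if (gamma > 0) {
    x <- x + rnorm(length(x), 0, gamma)
    y <- y + rnorm(length(y), 0, gamma)
  }
  similarity(x, y, measure)
}

#' Noise SD from the magnitude factor
#'
#' The noise SD is `gamma = s * x_min`, where `x_min` is the smallest
#' nonzero abundance in the table and `s` is the magnitude factor. The
#' conventional levels are none (`s = 0`), low (`s = 1`), medium
#' (`s = 10`) and high (`s = 100`).
#'
#' @param x An `abund_tbl` (typically relative abundances).
#' @param s Magnitude factor: a real >= 0 or one of `"none"`, `"low"`,
#'   `"medium"`, `"high"`.
#' @return The noise SD `gamma`.
#' @export
noise_gamma <- function(x, s = 1) {
  s <- resolve_magnitude(s)
  m <- abund_matrix(x)
  nz <- m[m > 0]
  if (length(nz) == 0) stop("table has no nonzero values", call. = FALSE)
  s * min(nz)
}

resolve_magnitude <- function(s) {
  if (is.character(s)) {
    levels <- c(none = 0, low = 1, medium = 10, high = 100)
    s <- levels[[match.arg(s, names(levels))]]
  }
  stopifnot(is.numeric(s), length(s) == 1, s >= 0)
  s
}

#' Benjamini-Yekutieli q-values
#'
#' Step-up false-discovery-rate adjustment with the dependence correction
#' factor `c(m) = sum_{k=1..m} 1/k`, valid under arbitrary dependence
#' between tests; q-values are capped at 1.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' adjust_q(c(0.01, 0.02, 0.03))  # all 0.055
#' @export
adjust_q <- function(pvalues) {
  if (length(pvalues) == 0) return(numeric(0))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  p.adjust(pvalues, method = "BY")
}

#' Z-statistic comparing bootstrap and permutation distributions
#'
#' The bootstrap distribution summarises the sampling variability of the
#' observed similarity; the permutation distribution is its null. The
#' default variant references the bootstrap mean against the permutation
#' null, `z = (boot_mean - perm_mean) / perm_sd`, which is calibrated
#' (uniform p under the null). The `"pooled"` variant divides by
#' `sqrt(boot_sd^2 + perm_sd^2)` instead and is markedly conservative;
#' it is provided as an alternative reading of the two-sample z-test.
#' P-values are two-sided normal tails, `p = 2 * pnorm(-|z|)`.
#'
#' @param boot_mean,boot_sd,perm_mean,perm_sd Numeric vectors (recycled).
#' @param variant `"permutation"` (default) or `"pooled"`.
#' @return A tibble with columns `z`, `p`; degenerate denominators give
#'   `NA` (pair skipped downstream).
#' @export
zscore_test <- function(boot_mean, boot_sd, perm_mean, perm_sd,
                        variant = c("permutation", "pooled")) {
  variant <- match.arg(variant)
  den <- switch(variant,
                permutation = perm_sd,
                pooled = sqrt(boot_sd^2 + perm_sd^2))
  z <- (boot_mean - perm_mean) / den
  z[!is.finite(z) | den <= 0] <- NA_real_
  tibble::tibble(z = z, p = 2 * pnorm(-abs(z)))
}

#' ReBoot significance test for all OTU pairs
#'
#' For every unordered pair of OTUs in the table, compares a bootstrap
#' distribution of the noise-injected similarity (samples resampled with
#' replacement) against a permutation null (each OTU's values permuted
#' across samples independently) with a two-sided z-test, and adjusts the
#' p-values with Benjamini-Yekutieli q-values over all testable pairs.
#'
#' When `renormalize` is on (default for relative tables, forbidden
#' otherwise), each permutation permutes the full table — including the
#' residual pool of OTUs excluded by the errthresh rule — and then
#' re-divides every sample by its new total before similarities are
#' extracted, preserving the sum-to-constant constraint of compositional
#' data. Noise is drawn fresh inside every bootstrap and permutation
#' iteration; the bootstrap and permutation phases use independent
#' iterations. A single RNG stream drives everything, so a fixed `seed`
#' makes the result bitwise reproducible.
#'
#' Associations are computed across all samples supplied, regardless of
#' their selection group or resource supply. Pairs whose similarity is
#' undefined (constant vectors) or whose z denominator is degenerate are
#' excluded from the output and from the multiple-testing family.
#'
#' @param x An `abund_tbl` that already passed [errthresh_filter()].
#' @param measure `"spearman"` (default) or `"pearson"`.
#' @param s Magnitude factor of the injected noise (number or level name,
#'   see [noise_gamma()]).
#' @param iterations Bootstrap/permutation iterations (>= 100; 1000 is the
#'   conventional setting).
#' @param renormalize Logical; defaults to `TRUE` for relative tables and
#'   `FALSE` otherwise. Turning it on for a non-relative table is an error.
#' @param residual_pool Optional tibble `sample_id`, `residual` from
#'   [errthresh_filter()]; used only when renormalizing.
#' @param variant z-test variant, see [zscore_test()].
#' @param seed Optional integer seed.
#' @return A tibble of class `association_results` with one row per
#'   testable pair: `otu_a`, `otu_b`, `similarity`, `boot_mean`,
#'   `boot_sd`, `perm_mean`, `perm_sd`, `z`, `p`, `q`.
#' @export
reboot <- function(x, measure = c("spearman", "pearson"), s = 1,
                   iterations = 1000, renormalize = NULL,
                   residual_pool = NULL,
                   variant = c("permutation", "pooled"), seed = NULL) {
  stopifnot(inherits(x, "abund_tbl"))
  measure <- match.arg(measure)
  variant <- match.arg(variant)
  if (iterations < 100) stop("need at least 100 iterations", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  kind <- abundance_kind(x)
  if (is.null(renormalize)) renormalize <- kind == "relative"
  if (renormalize && kind != "relative") {
    stop("renormalization is only meaningful for relative abundances; ",
         "call with renormalize = FALSE for ", kind, " tables",
         call. = FALSE)
  }
  m <- abund_matrix(x)
  n <- nrow(m); p <- ncol(m)
  if (n < 3) stop("need at least 3 samples", call. = FALSE)
  if (p < 2) stop("need at least 2 OTUs", call. = FALSE)
  gamma <- if (resolve_magnitude(s) > 0) noise_gamma(x, s) else 0

  rp <- rep(0, n)
  if (!is.null(residual_pool)) {
    rp <- residual_pool$residual[match(rownames(m),
                                       residual_pool$sample_id)]
    if (anyNA(rp)) stop("residual_pool must cover every sample", call. = FALSE)
  }

  cor_noisy <- function(mat) {
    if (gamma > 0) {
      mat <- mat + matrix(rnorm(length(mat), 0, gamma), nrow(mat))
    }
    suppressWarnings(cor(mat, method = measure))
  }

  accumulate <- function(draw) {
    s1 <- sq <- nn <- matrix(0, p, p)
    for (b in seq_len(iterations)) {
      cm <- draw()
      ok <- is.finite(cm)
      cm[!ok] <- 0
      s1 <- s1 + cm
      sq <- sq + cm * cm
      nn <- nn + ok
    }
    mean <- s1 / nn
    var <- (sq - nn * mean^2) / (nn - 1)
    list(mean = mean, sd = sqrt(pmax(var, 0)), n = nn)
  }

  point <- cor_noisy(m)
  boot <- accumulate(function() {
    cor_noisy(m[sample.int(n, n, replace = TRUE), , drop = FALSE])
  })
  perm <- accumulate(function() {
    mp <- m
    for (j in seq_len(p)) mp[, j] <- mp[sample.int(n), j]
    if (renormalize) {
      tot <- rowSums(mp) + rp[sample.int(n)]
      tot[tot == 0] <- 1
      mp <- mp / tot
    }
    cor_noisy(mp)
  })

  ut <- which(upper.tri(point), arr.ind = TRUE)
  res <- tibble::tibble(
    otu_a = colnames(m)[ut[, 1]],
    otu_b = colnames(m)[ut[, 2]],
    similarity = point[ut],
    boot_mean = boot$mean[ut],
    boot_sd = boot$sd[ut],
    perm_mean = perm$mean[ut],
    perm_sd = perm$sd[ut])
  zt <- zscore_test(res$boot_mean, res$boot_sd, res$perm_mean, res$perm_sd,
                    variant = variant)
  res$z <- zt$z
  res$p <- zt$p
  keep <- is.finite(res$similarity) & is.finite(res$z) &
    boot$n[ut] >= 2 & perm$n[ut] >= 2
  res <- res[keep, , drop = FALSE]
  res$q <- adjust_q(res$p)
  class(res) <- c("association_results", class(res))
  res
}
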