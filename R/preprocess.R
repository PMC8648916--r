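#' Convert counts to relative abundances
#'
#' Each sample's counts are divided by its total reads. No correction for
#' unequal sequencing depth is applied beyond this: the totals themselves
#' carry no information downstream unless re-introduced via
#' [to_absolute()].
#'
#' @param x An `abund_tbl` of kind `"counts"`.
#' @return An `abund_tbl` of kind `"relative"`; every row sums to 1.
#' @export
to_relative <- function(x) {
  stopifnot(inherits(x, "abund_tbl"))
  if (abundance_kind(x) != "counts") {
    stop("to_relative() expects a counts table", call. = FALSE)
  }
  m <- abund_matrix(x)
  tot <- rowSums(m)
  zero <- which(tot == 0)
  if (length(zero)) {
    stop("all-zero sample: ", rownames(m)[zero[1]], call. = FALSE)
  }
  abundance_table(m / tot, "relative")
}

#' Filter OTUs by maximum relative abundance
#'
#' Removes OTUs whose maximum relative abundance across all samples falls
#' below a threshold, to avoid noise and spurious correlations from rare
#' taxa. The named levels are `high` = 5e-3, `medium` = 1e-3 and
#' `low` = 5e-4 (count proportions); any explicit positive threshold is
#' also accepted. An OTU is kept iff its maximum is `>=` the threshold.
#'
#' @param x An `abund_tbl` of kind `"relative"`.
#' @param level `"high"`, `"medium"`, `"low"`, or a positive number.
#' @return A list with `table` (the filtered `abund_tbl`) and `report`
#'   (a `filter_report` with `kept_otu_ids`, `dropped_otu_ids`,
#'   `threshold`).
#' @export
filter_by_max_abundance <- function(x, level = "low") {
  stopifnot(inherits(x, "abund_tbl"))
  if (abundance_kind(x) != "relative") {
    stop("filter_by_max_abundance() expects a relative table", call. = FALSE)
  }
  thresholds <- c(high = 5e-3, medium = 1e-3, low = 5e-4)
  threshold <- if (is.character(level)) {
    level <- match.arg(level, names(thresholds))
    thresholds[[level]]
  } else {
    as.numeric(level)
  }
  if (!is.finite(threshold) || threshold <= 0) {
    stop("filtering threshold must be positive", call. = FALSE)
  }
  m <- abund_matrix(x)
  maxima <- apply(m, 2, max)
  kept <- colnames(m)[maxima >= threshold]
  dropped <- setdiff(colnames(m), kept)
  list(table = keep_otus(x, kept),
       report = new_filter_report(kept, dropped, threshold, NULL))
}

new_filter_report <- function(kept, dropped, threshold, residual_pool) {
  structure(list(kept_otu_ids = kept, dropped_otu_ids = dropped,
                 threshold = threshold, residual_pool = residual_pool),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("# Filter report: %d kept, %d dropped (threshold %.4g)\n",
              length(x$kept_otu_ids), length(x$dropped_otu_ids),
              x$threshold))
  invisible(x)
}

#' Scale relative abundances to absolute abundances
#'
#' Multiplies each sample's relative abundances by its estimated total
#' bacterial cell density (e.g. from flow cytometry), so that values are
#' on a cells-per-volume scale. Ranks within a sample are unchanged; ranks
#' of an OTU across samples change whenever densities differ.
#'
#' @param x An `abund_tbl` of kind `"relative"`.
#' @param densities Tibble with columns `sample_id`, `density`
#'   (all positive), covering every sample of `x`.
#' @return An `abund_tbl` of kind `"absolute"`.
#' @export
to_absolute <- function(x, densities) {
  stopifnot(inherits(x, "abund_tbl"))
  if (abundance_kind(x) != "relative") {
    stop("to_absolute() expects a relative table", call. = FALSE)
  }
  d <- densities$density[match(x$sample_id, densities$sample_id)]
  if (anyNA(d)) {
    stop("missing density for sample: ",
         x$sample_id[which(is.na(d))[1]], call. = FALSE)
  }
  if (any(d <= 0)) {
    stop("densities must be positive", call. = FALSE)
  }
  abundance_table(abund_matrix(x) * d, "absolute")
}

#' Prevalence-based exclusion of rare OTUs (errthresh rule)
#'
#' With `n` samples, an OTU absent (zero) in more than `n * 10^(-4/n)`
#' samples is excluded from association testing. "More than" is strict: a
#' zero-count exactly at the cutoff keeps the OTU. The summed relative
#' mass of the excluded OTUs is recorded per sample as the residual pool,
#' so the excluded OTUs still take part in permutation renormalization
#' (see [reboot()]). Zeros are counted on the working table supplied at
#' association time.
#'
#' @param x An `abund_tbl` (any kind).
#' @return A list with `table` (filtered `abund_tbl`) and `report`
#'   (a `filter_report` whose `threshold` is the cutoff `n * 10^(-4/n)`
#'   and whose `residual_pool` is a tibble `sample_id`, `residual` of the
#'   per-sample summed relative abundance of excluded OTUs).
#' @examples
#' # n = 4 samples: cutoff 4 * 10^-1 = 0.4, so any zero excludes the OTU
#' @export
errthresh_filter <- function(x) {
  stopifnot(inherits(x, "abund_tbl"))
  m <- abund_matrix(x)
  n <- nrow(m)
  stopifnot(n >= 1)
  cutoff <- n * 10^(-4 / n)
  zeros <- colSums(m == 0)
  kept <- colnames(m)[zeros <= cutoff]
  dropped <- setdiff(colnames(m), kept)
  rel <- if (abundance_kind(x) == "relative") m else m / pmax(rowSums(m), .Machine$double.xmin)
  residual <- if (length(dropped)) {
    unname(rowSums(rel[, dropped, drop = FALSE]))
  } else {
    rep(0, n)
  }
  pool <- tibble::tibble(sample_id = rownames(m), residual = residual)
  list(table = keep_otus(x, kept),
       report = new_filter_report(kept, dropped, cutoff, pool))
}
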