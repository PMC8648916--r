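#' Per-day z-score decomposition of OTU trajectories
#'
#' For one facet (selection group x resource supply), averages each OTU's
#' abundance over the replicate microcosms per sampling day, then
#' standardises the day-mean series with its mean and population standard
#' deviation (1/N form):
#' `z[i, k] = (x[i, ., k] - x[., ., k]) / sigma_k`.
#' Days missing in one replicate are averaged over the available
#' replicates rather than dropped. OTUs with a constant day-mean series
#' (`sigma_k = 0`) get `NA` z-scores and are shown grey throughout.
#'
#' With `basis = "rank"` the raw abundances are first replaced, per OTU
#' within each microcosm, by the ranks of that OTU's trajectory across its
#' sampling days; all subsequent calculations are identical. This is the
#' variant matching Spearman-correlation networks: with a single
#' replicate, the mean over days of `z[i,k] * z[i,l]` is exactly the
#' Spearman correlation of OTUs k and l (see
#' [correlation_identity()]). Rank-basis outputs are invariant under any
#' strictly increasing transform of the abundances.
#'
#' @param x An `abund_tbl`.
#' @param metadata Sample metadata tibble (with `current_regime` derived,
#'   see [read_sample_metadata()] / [add_current_regime()]).
#' @param group Selection group of the facet, `"RK"` or `"KR"`.
#' @param supply Resource supply of the facet, `"H"` or `"L"`.
#' @param basis `"raw"` or `"rank"`.
#' @return A tibble of class `temporal_profile` with columns `otu_id`,
#'   `day`, `day_mean`, `series_mean`, `series_sd`, `z`; attributes
#'   `facet`, `basis` and `n_days`.
#' @export
temporal_profile <- function(x, metadata, group, supply,
                             basis = c("raw", "rank")) {
  basis <- match.arg(basis)
  stopifnot(group %in% c("RK", "KR"), supply %in% c("H", "L"))
  meta <- dplyr::filter(metadata, .data$selection_group == group,
                        .data$resource_supply == supply)
  if (nrow(meta) == 0) stop("no samples in the requested facet", call. = FALSE)
  long <- tidyr::pivot_longer(tibble::as_tibble(x),
                              -"sample_id", names_to = "otu_id",
                              values_to = "value")
  long <- dplyr::inner_join(long,
                            meta[c("sample_id", "microcosm_id", "day")],
                            by = "sample_id")
  if (basis == "rank") {
    long <- dplyr::mutate(
      dplyr::group_by(long, .data$microcosm_id, .data$otu_id),
      value = rank(.data$value))
    long <- dplyr::ungroup(long)
  }
  prof <- dplyr::summarise(
    dplyr::group_by(long, .data$otu_id, .data$day),
    day_mean = mean(.data$value), .groups = "drop")
  prof <- dplyr::mutate(
    dplyr::group_by(prof, .data$otu_id),
    series_mean = mean(.data$day_mean),
    series_sd = sqrt(mean((.data$day_mean - .data$series_mean)^2)),
    z = ifelse(.data$series_sd > 0,
               (.data$day_mean - .data$series_mean) / .data$series_sd,
               NA_real_))
  prof <- dplyr::arrange(dplyr::ungroup(prof), .data$otu_id, .data$day)
  structure(prof,
            class = c("temporal_profile", class(prof)),
            facet = c(selection_group = group, resource_supply = supply),
            basis = basis,
            n_days = length(unique(prof$day)))
}

#' Mean over available replicates for one OTU and day
#'
#' @param x Numeric vector of replicate abundances; `NA`s (missing
#'   replicates) are dropped.
#' @return The arithmetic mean, or `NA` if no replicate is present.
#' @export
day_mean <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) return(NA_real_)
  mean(x)
}

#' Standardise a day-mean series with its population SD
#'
#' `z = (x - mean(x)) / sigma` with `sigma = sqrt(mean((x - mean(x))^2))`
#' (1/N, not 1/(N-1)), so that `mean(z) = 0` and the population SD of `z`
#' is exactly 1. A constant series returns all-`NA`.
#'
#' @param x Numeric vector of day means (length >= 2).
#' @return Numeric vector of z-scores.
#' @examples
#' zscore_series(c(2, 4, 6))  # -1.2247, 0, 1.2247
#' @export
zscore_series <- function(x) {
  stopifnot(length(x) >= 2)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0) return(rep(NA_real_, length(x)))
  (x - mu) / sigma
}

#' Correlation from z-score products
#'
#' `rho = (1/N) * sum_i z[i,k] * z[i,l]` equals the Pearson correlation of
#' the two day-mean series (with population standardisation this is an
#' identity, not an approximation). On the rank basis with one replicate
#' it equals the Spearman correlation of the two OTUs' trajectories.
#'
#' @param z_k,z_l Z-score vectors of equal length over the same days.
#' @return The correlation.
#' @export
correlation_identity <- function(z_k, z_l) {
  if (length(z_k) != length(z_l)) {
    stop("z-score series must cover the same days", call. = FALSE)
  }
  mean(z_k * z_l)
}

#' Node colour and size from a per-day z-score
#'
#' Black if `z < -1` (below-average abundance that day), grey if
#' `-1 <= z <= 1`, orange if `z > 1`; bounds inclusive on the grey side.
#' Size is `a + b * |z|`, so deviant nodes are drawn larger. A missing z
#' (constant series) maps to grey with size `a`.
#'
#' @param z Numeric vector of z-scores (may contain `NA`).
#' @param a,b Positive size constants (display units).
#' @return A tibble with columns `colour`, `size`.
#' @export
node_style <- function(z, a = 2, b = 2) {
  stopifnot(a > 0, b > 0)
  colour <- dplyr::case_when(
    is.na(z) ~ "grey",
    z < -1 ~ "black",
    z > 1 ~ "orange",
    TRUE ~ "grey")
  size <- ifelse(is.na(z), a, a + b * abs(z))
  tibble::tibble(colour = colour, size = size)
}

#' Edge colour from the product of endpoint z-scores
#'
#' Red if `z_k * z_l < -0.3` (contribution to a negative association that
#' day), blue if `> 0.3` (positive contribution), grey in between (bounds
#' inclusive). Any missing input maps to grey.
#'
#' @param z_k,z_l Numeric vectors of endpoint z-scores (recycled).
#' @param cut Product cutoff (default 0.3).
#' @return Character vector of `"red"`, `"grey"`, `"blue"`.
#' @export
edge_style <- function(z_k, z_l, cut = 0.3) {
  prod <- z_k * z_l
  dplyr::case_when(
    is.na(prod) ~ "grey",
    prod < -cut ~ "red",
    prod > cut ~ "blue",
    TRUE ~ "grey")
}

#' Styled snapshot of a network on one sampling day
#'
#' Joins a temporal profile onto the network's nodes and edges for one
#' day, applying the node and edge style rules.
#'
#' @param net A `cooccur_network`.
#' @param profile A [temporal_profile()].
#' @param day Sampling day present in the profile.
#' @param a,b Node size constants.
#' @param cut Edge product cutoff.
#' @return A list with styled `nodes` and `edges` tibbles.
#' @export
style_network_day <- function(net, profile, day, a = 2, b = 2, cut = 0.3) {
  stopifnot(inherits(net, "cooccur_network"))
  pd <- dplyr::filter(tibble::as_tibble(profile), .data$day == !!day)
  if (nrow(pd) == 0) stop("day ", day, " not present in profile", call. = FALSE)
  nodes <- dplyr::left_join(net$nodes, pd[c("otu_id", "z")], by = "otu_id")
  nodes <- dplyr::bind_cols(nodes, node_style(nodes$z, a = a, b = b))
  zmap <- setNames(pd$z, pd$otu_id)
  edges <- dplyr::mutate(net$edges,
                         z_a = zmap[.data$otu_a],
                         z_b = zmap[.data$otu_b],
                         colour = edge_style(.data$z_a, .data$z_b, cut = cut))
  list(nodes = nodes, edges = edges)
}

#' Mean per-day z-product for every network edge
#'
#' For each edge, the mean over days of the product of its endpoints'
#' z-scores — i.e. the correlation of the two day-mean series (see
#' [correlation_identity()]). Coordinated OTU pairs give positive values,
#' anti-coordinated pairs negative ones, linking the temporal dynamics
#' back to the association signs of the network.
#'
#' @param net A `cooccur_network`.
#' @param profile A [temporal_profile()].
#' @return The edge tibble with a `mean_z_product` column.
#' @export
edge_z_products <- function(net, profile) {
  stopifnot(inherits(net, "cooccur_network"))
  prof <- tibble::as_tibble(profile)
  zwide <- tidyr::pivot_wider(prof[c("otu_id", "day", "z")],
                              names_from = "otu_id", values_from = "z")
  dplyr::mutate(net$edges, mean_z_product = purrr::map2_dbl(
    .data$otu_a, .data$otu_b, function(ka, kb) {
      if (!ka %in% names(zwide) || !kb %in% names(zwide)) return(NA_real_)
      mean(zwide[[ka]] * zwide[[kb]])
    }))
}
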