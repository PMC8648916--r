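#' Configuration for the selection-switch microcosm simulator
#'
#' The generator emulates a 2 x 2 factorial crossover design: selection
#' group (RK starts under r-selection, KR under K-selection, switched
#' between days 28 and 29) crossed with resource supply (H/L), each cell
#' replicated, 12 microcosms in total by default, sampled at 17 days over a
#' 50-day run. Each OTU belongs to a guild: K-strategists are favoured under
#' continuous feeding (K-regime), r-strategists under pulse feeding
#' (r-regime), neutral OTUs respond to neither.
#'
#' Latent log-abundances follow
#' `baseline_k + guild_effect * favoured(k, regime) + AR(1) noise`, where
#' `favoured` is +1 when the current regime matches the guild, -1 when it
#' opposes it and 0 for neutral OTUs. Reads are drawn multinomially with a
#' lognormal library size around `depth`; per-sample total densities scale
#' `density_base` by the summed latent abundance.
#'
#' @param n_k_otus,n_r_otus,n_neutral_otus Number of OTUs per guild.
#' @param n_microcosms Total microcosms; must be a multiple of 4
#'   (2 groups x 2 supplies), replicates = `n_microcosms / 4`.
#' @param days Ordered integer sampling days within 1..50; the regime
#'   switch falls between days 28 and 29.
#' @param depth Expected reads per sample.
#' @param depth_sd Lognormal SD (log units) of the library size.
#' @param guild_effect Log-scale abundance shift of a guild under its
#'   favoured regime (> 0).
#' @param ar_coef AR(1) coefficient of the temporal noise on the log scale.
#' @param noise_sd Stationary SD of the AR(1) log-scale noise.
#' @param baseline_sd SD of the lognormal OTU baselines (log units); a wide
#'   value gives a realistic rank-abundance curve and leaves a handful of
#'   OTUs below the relative-abundance filtering thresholds.
#' @param density_base Expected total cells per mL under high resource
#'   supply at the average community size.
#' @param supply_density_ratio Multiplier applied to densities of
#'   low-supply microcosms.
#' @param disturbance If `TRUE`, an extra lognormal shock of SD
#'   `disturbance_sd` is added on the first sampling day and on the first
#'   day after the regime switch (the two instability periods); off by
#'   default.
#' @param disturbance_sd SD of the optional shock (log units).
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @return A list of class `sim_config`.
#' @export
simulation_config <- function(n_k_otus = 30, n_r_otus = 30,
                              n_neutral_otus = 20,
                              n_microcosms = 12,
                              days = c(1, 2, 4, 8, 12, 16, 20, 24, 28,
                                       29, 32, 36, 40, 43, 46, 48, 50),
                              depth = 6e4, depth_sd = 0.3,
                              guild_effect = 2, ar_coef = 0.5,
                              noise_sd = 0.5, baseline_sd = 1.5,
                              density_base = 1e6,
                              supply_density_ratio = 0.5,
                              disturbance = FALSE, disturbance_sd = 1,
                              seed = NULL) {
  stopifnot(n_k_otus >= 0, n_r_otus >= 0, n_neutral_otus >= 0,
            guild_effect >= 0, depth >= 1, noise_sd >= 0,
            abs(ar_coef) < 1, n_microcosms >= 4,
            n_microcosms %% 4 == 0, all(diff(days) > 0), all(days >= 1))
  structure(as.list(environment()), class = "sim_config")
}

# stationary AR(1) series of length n with marginal SD sigma
ar1_noise <- function(n, phi, sigma) {
  e <- numeric(n)
  e[1] <- rnorm(1, 0, sigma)
  if (n > 1) {
    innov_sd <- sigma * sqrt(1 - phi^2)
    for (i in 2:n) e[i] <- phi * e[i - 1] + rnorm(1, 0, innov_sd)
  }
  e
}

#' Generate a synthetic selection-switch experiment
#'
#' Draws OTU baselines, simulates guild-structured latent dynamics per
#' microcosm, samples reads multinomially and derives total-density
#' scalars. Ground truth (guild membership per OTU) is returned so module
#' detection downstream can be scored against the planted partition.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `counts` (an `abund_tbl` of kind counts),
#'   `metadata` (tibble with `current_regime`), `density` (tibble
#'   `sample_id`, `density`) and `truth` (tibble `otu_id`, `guild`).
#' @examples
#' sim <- generate_experiment(simulation_config(
#'   n_k_otus = 4, n_r_otus = 4, n_neutral_otus = 0,
#'   n_microcosms = 4, days = c(1, 14, 28, 29, 40, 50),
#'   depth = 1000, seed = 1))
#' sim$counts
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_otu <- config$n_k_otus + config$n_r_otus + config$n_neutral_otus
  if (n_otu < 1) stop("config yields zero OTUs", call. = FALSE)
  if (length(config$days) < 1) stop("config yields zero samples", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  guild <- rep(c("K", "r", "neutral"),
               c(config$n_k_otus, config$n_r_otus, config$n_neutral_otus))
  otu_id <- sprintf("%s_%03d", ifelse(guild == "neutral", "n", guild),
                    stats::ave(seq_len(n_otu), guild, FUN = seq_along))
  truth <- tibble::tibble(otu_id = otu_id, guild = guild)

  reps <- config$n_microcosms / 4
  design <- tidyr::expand_grid(selection_group = c("RK", "KR"),
                               resource_supply = c("H", "L"),
                               replicate = seq_len(reps))
  design$microcosm_id <- sprintf("%s_%s_%d", design$selection_group,
                                 design$resource_supply, design$replicate)

  days <- config$days
  n_day <- length(days)
  baseline <- rnorm(n_otu, 0, config$baseline_sd)
  # +1 under matching regime, -1 under the opposite, 0 for neutral
  fav <- function(g, regime) {
    ifelse(g == "neutral", 0, ifelse(g == regime, 1, -1))
  }
  post_switch_first <- match(TRUE, days >= 29)

  meta <- list(); counts <- list(); latent_tot <- list()
  for (m in seq_len(nrow(design))) {
    row <- design[m, ]
    regime <- current_regime(rep(row$selection_group, n_day), days)
    shift <- outer(regime, guild, function(rg, g) fav(g, rg)) *
      config$guild_effect
    eps <- vapply(seq_len(n_otu), function(k) {
      ar1_noise(n_day, config$ar_coef, config$noise_sd)
    }, numeric(n_day))
    if (config$disturbance) {
      shock_days <- c(1L, post_switch_first)
      shock_days <- shock_days[!is.na(shock_days)]
      eps[shock_days, ] <- eps[shock_days, ] +
        rnorm(length(shock_days) * n_otu, 0, config$disturbance_sd)
    }
    latent <- exp(sweep(shift + eps, 2, baseline, "+"))
    sample_id <- sprintf("%s_d%02d", row$microcosm_id, days)
    lib <- pmax(1, round(rlnorm(n_day, log(config$depth), config$depth_sd)))
    cnt <- t(vapply(seq_len(n_day), function(i) {
      as.numeric(rmultinom(1, lib[i], latent[i, ]))
    }, numeric(n_otu)))
    dimnames(cnt) <- list(sample_id, otu_id)
    counts[[m]] <- cnt
    latent_tot[[m]] <- rowSums(latent)
    meta[[m]] <- tibble::tibble(sample_id = sample_id,
                                microcosm_id = row$microcosm_id,
                                day = as.integer(days),
                                selection_group = row$selection_group,
                                resource_supply = row$resource_supply,
                                replicate = as.integer(row$replicate))
  }
  metadata <- add_current_regime(dplyr::bind_rows(meta))
  validate_metadata(metadata)
  cnt <- do.call(rbind, counts)
  tot <- unlist(latent_tot)
  supply_mult <- ifelse(metadata$resource_supply == "H", 1,
                        config$supply_density_ratio)
  density <- tibble::tibble(
    sample_id = metadata$sample_id,
    density = config$density_base * supply_mult * tot / mean(tot))

  list(counts = abundance_table(cnt, "counts"),
       metadata = metadata,
       density = density,
       truth = truth)
}

#' Score recovery of the planted guilds by a detected module partition
#'
#' Computes the adjusted Rand index (ARI) between the detected module
#' partition and the planted guild partition, over the OTUs present (with a
#' non-missing module) in both. 1 means perfect recovery, ~0 chance level.
#'
#' @param modules A tibble with columns `otu_id` and `module` (as returned
#'   in the `nodes` element of a detected network); rows with missing
#'   `module` are excluded.
#' @param truth A tibble with columns `otu_id` and `guild` (the `truth`
#'   element of [generate_experiment()]).
#' @return The adjusted Rand index, a real in \[-1, 1\].
#' @export
guild_recovery_score <- function(modules, truth) {
  joined <- dplyr::inner_join(
    dplyr::filter(modules, !is.na(.data$module)),
    truth, by = "otu_id")
  if (nrow(joined) == 0) {
    stop("no OTUs shared between detected modules and truth", call. = FALSE)
  }
  mclust::adjustedRandIndex(joined$module, joined$guild)
}
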