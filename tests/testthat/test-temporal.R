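test_that("day means average the available replicates", {
  expect_equal(day_mean(c(1, 2, 3)), 2)
  expect_equal(day_mean(5), 5)
  expect_equal(day_mean(c(4, NA, 2)), 3)  # missing replicate dropped
  expect_true(is.na(day_mean(c(NA, NA))))
})

test_that("z-scores standardise with the population (1/N) SD", {
  z <- zscore_series(c(2, 4, 6))
  expect_equal(z, c(-1, 0, 1) * 2 / sqrt(8 / 3), tolerance = 1e-12)
  expect_equal(z[1], -1.2247, tolerance = 1e-4)
  set.seed(13)
  for (i in 1:20) {
    x <- rnorm(sample(3:30, 1))
    z <- zscore_series(x)
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-10)
  }
  expect_true(all(is.na(zscore_series(rep(3, 5)))))
})

test_that("temporal profiles have mean-zero, unit-SD z per OTU", {
  sim <- generate_experiment(small_config())
  prof <- temporal_profile(to_relative(sim$counts), sim$metadata,
                          group = "RK", supply = "H")
  stats <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(prof), otu_id),
    mu = mean(z), sd = sqrt(mean(z^2)))
  ok <- !is.na(stats$mu)
  expect_true(all(abs(stats$mu[ok]) < 1e-10))
  expect_true(all(abs(stats$sd[ok] - 1) < 1e-10))
  expect_equal(attr(prof, "n_days"), length(small_config()$days))
})

test_that("z-product mean reproduces the Pearson correlation of day means", {
  expect_equal(correlation_identity(zscore_series(c(2, 4, 6)),
                                    zscore_series(c(6, 4, 2))), -1,
               tolerance = 1e-12)
  z <- zscore_series(c(1, 5, 2, 8))
  expect_equal(correlation_identity(z, z), 1, tolerance = 1e-12)
  set.seed(14)
  for (i in 1:100) {
    n <- sample(3:20, 1)
    a <- rnorm(n); b <- rnorm(n)
    expect_equal(correlation_identity(zscore_series(a), zscore_series(b)),
                 cor(a, b), tolerance = 1e-10)
  }
  expect_error(correlation_identity(1:3, 1:4), "same days")
})

test_that("rank basis with one replicate yields the Spearman correlation", {
  # 4 microcosms = 1 replicate per (group, supply) facet
  sim <- generate_experiment(small_config())
  prof <- temporal_profile(to_relative(sim$counts), sim$metadata,
                           group = "KR", supply = "L", basis = "rank")
  wide <- tidyr::pivot_wider(tibble::as_tibble(prof)[c("otu_id", "day", "z")],
                             names_from = "otu_id", values_from = "z")
  raw <- to_relative(sim$counts)
  meta <- dplyr::filter(sim$metadata, selection_group == "KR",
                        resource_supply == "L")
  meta <- dplyr::arrange(meta, day)
  m <- abund_matrix(raw)[meta$sample_id, ]
  ids <- otu_ids(raw)
  for (pair in list(c(1, 2), c(3, 9), c(5, 17))) {
    k <- ids[pair[1]]; l <- ids[pair[2]]
    rho <- correlation_identity(wide[[k]], wide[[l]])
    expect_equal(rho, cor(m[, k], m[, l], method = "spearman"),
                 tolerance = 1e-10)
  }
})

test_that("rank-basis outputs are invariant under monotone transforms", {
  sim <- generate_experiment(small_config())
  rel <- to_relative(sim$counts)
  warped <- abundance_table(exp(5 * abund_matrix(rel)) - 1, "counts")
  p1 <- temporal_profile(rel, sim$metadata, "RK", "H", basis = "rank")
  p2 <- temporal_profile(warped, sim$metadata, "RK", "H", basis = "rank")
  expect_equal(p1$z, p2$z, tolerance = 1e-12)
  expect_equal(p1$day_mean, p2$day_mean, tolerance = 1e-12)
})

test_that("node colours split at z = -1 and 1 with inclusive grey bounds", {
  st <- node_style(c(-1.2247, -1, 0, 1, 2, NA), a = 1, b = 2)
  expect_equal(st$colour, c("black", "grey", "grey", "grey", "orange", "grey"))
  expect_equal(st$size, c(1 + 2 * 1.2247, 3, 1, 3, 5, 1))
})

test_that("edge colours split at |product| = 0.3 with inclusive grey bounds", {
  expect_equal(edge_style(-1.2247, 1.2247), "red")  # product -1.5
  expect_equal(edge_style(0.5, 0.5), "grey")        # 0.25
  expect_equal(edge_style(1, 1), "blue")
  expect_equal(edge_style(0.3, 1), "grey")          # exactly 0.3
  expect_equal(edge_style(-0.3, 1), "grey")         # exactly -0.3
  expect_equal(edge_style(NA, 2), "grey")
})

test_that("styled day snapshots join z-scores onto the network", {
  sim <- generate_experiment(small_config())
  rel <- to_relative(sim$counts)
  res <- reboot(filter_by_max_abundance(rel, "low")$table,
                s = 0, iterations = 100, seed = 31)
  net <- detect_modules(build_network(select_edges(res, "top_k", k = 20)))
  prof <- temporal_profile(rel, sim$metadata, "RK", "H", basis = "rank")
  day <- small_config()$days[3]
  styled <- style_network_day(net, prof, day)
  expect_true(all(styled$nodes$colour %in% c("black", "grey", "orange")))
  expect_true(all(styled$edges$colour %in% c("red", "grey", "blue")))
  expect_error(style_network_day(net, prof, 999), "not present")
})

test_that("edge signs agree with the mean per-day z-product for coordinated guilds", {
  cfg <- simulation_config(n_k_otus = 8, n_r_otus = 8, n_neutral_otus = 0,
                           n_microcosms = 12, guild_effect = 2.5,
                           depth = 3000, seed = 17)
  sim <- generate_experiment(cfg)
  rel <- to_relative(sim$counts)
  res <- reboot(filter_by_max_abundance(rel, "low")$table,
                s = "low", iterations = 150, seed = 18)
  net <- detect_modules(build_network(select_edges(res, "top_k", k = 40)))
  prof <- temporal_profile(rel, sim$metadata, "RK", "H", basis = "rank")
  prods <- edge_z_products(net, prof)
  ok <- is.finite(prods$mean_z_product)
  agree <- sign(prods$mean_z_product[ok]) ==
    ifelse(prods$sign[ok] == "+", 1, -1)
  expect_gt(mean(agree), 0.9)
})
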