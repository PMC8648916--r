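test_that("to_relative normalises each sample to proportions", {
  m <- matrix(c(2, 2,
                1, 3), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  rel <- to_relative(abundance_table(m, "counts"))
  expect_equal(unname(abund_matrix(rel)["s1", ]), c(0.5, 0.5))
  expect_equal(abundance_kind(rel), "relative")
  m2 <- matrix(c(1, 0, 3), 1, 3,
               dimnames = list("s1", c("a", "b", "c")))
  rel2 <- to_relative(abundance_table(m2, "counts"))
  expect_equal(unname(abund_matrix(rel2)[1, ]), c(0.25, 0, 0.75))
})

test_that("to_relative row sums are exactly 1 and all-zero samples are rejected", {
  sim <- generate_experiment(small_config())
  rel <- to_relative(sim$counts)
  expect_true(all(abs(rowSums(abund_matrix(rel)) - 1) < 1e-12))
  m <- matrix(c(1, 2, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("ok", "empty"), c("a", "b")))
  expect_error(to_relative(abundance_table(m, "counts")), "empty")
})

test_that("max-abundance filter honours the three named thresholds", {
  # OTU maxima 0.01, 0.002, 0.0004 split the three levels
  m <- rbind(s1 = c(0.01, 0.002, 0.0004),
             s2 = c(0.005, 0.001, 0.0002))
  m <- cbind(m, filler = 1 - rowSums(m))
  colnames(m)[1:3] <- c("big", "mid", "tiny")
  rel <- abundance_table(m, "relative")
  kept <- function(level) {
    setdiff(filter_by_max_abundance(rel, level)$report$kept_otu_ids, "filler")
  }
  expect_equal(kept("high"), "big")
  expect_equal(kept("medium"), c("big", "mid"))
  expect_equal(kept("low"), c("big", "mid"))  # 0.0004 < 5e-4
  expect_equal(kept(4e-4), c("big", "mid", "tiny"))
  expect_error(filter_by_max_abundance(rel, 0), "positive")
})

test_that("filter kept-sets nest monotonically and filtering is idempotent", {
  sim <- generate_experiment(small_config())
  rel <- to_relative(sim$counts)
  k_high <- filter_by_max_abundance(rel, "high")$report$kept_otu_ids
  k_med <- filter_by_max_abundance(rel, "medium")$report$kept_otu_ids
  k_low <- filter_by_max_abundance(rel, "low")$report$kept_otu_ids
  expect_true(all(k_high %in% k_med))
  expect_true(all(k_med %in% k_low))
  once <- filter_by_max_abundance(rel, "medium")$table
  twice <- filter_by_max_abundance(once, "medium")$table
  expect_identical(abund_matrix(once), abund_matrix(twice))
})

test_that("absolute scaling multiplies by density and preserves ranks under equal densities", {
  m <- rbind(s1 = c(0.5, 0.5), s2 = c(0.2, 0.8))
  colnames(m) <- c("a", "b")
  rel <- abundance_table(m, "relative")
  dens <- tibble::tibble(sample_id = c("s1", "s2"), density = c(1e6, 2e6))
  abs_tab <- to_absolute(rel, dens)
  expect_equal(unname(abund_matrix(abs_tab)["s1", ]), c(5e5, 5e5))
  expect_equal(abundance_kind(abs_tab), "absolute")
  # conservation: row sums recover the density vector
  expect_equal(unname(rowSums(abund_matrix(abs_tab))), dens$density,
               tolerance = 1e-9)
  # equal densities leave between-OTU Spearman correlations untouched
  sim <- generate_experiment(small_config())
  rel2 <- to_relative(sim$counts)
  dens2 <- tibble::tibble(sample_id = rel2$sample_id, density = 3e6)
  abs2 <- to_absolute(rel2, dens2)
  expect_equal(cor(abund_matrix(abs2), method = "spearman"),
               cor(abund_matrix(rel2), method = "spearman"),
               tolerance = 1e-12)
  expect_error(to_absolute(rel, dens[1, ]), "missing density")
  expect_error(to_absolute(rel, dplyr::mutate(dens, density = 0)), "positive")
})

test_that("errthresh rule excludes OTUs absent in more than n * 10^(-4/n) samples", {
  # n = 202: cutoff just below 193, so 193 zeros excluded, 192 kept
  n <- 202
  cutoff <- n * 10^(-4 / n)
  expect_gt(cutoff, 192.9)
  expect_lt(cutoff, 193)
  m <- cbind(z193 = c(rep(0, 193), rep(5, n - 193)),
             z192 = c(rep(0, 192), rep(5, n - 192)),
             full = rep(3, n))
  rownames(m) <- sprintf("s%03d", seq_len(n))
  res <- errthresh_filter(abundance_table(m, "counts"))
  expect_equal(res$report$dropped_otu_ids, "z193")
  expect_setequal(res$report$kept_otu_ids, c("z192", "full"))
  expect_equal(res$report$threshold, cutoff)
})

test_that("errthresh at n = 4 excludes any OTU with a zero; full-prevalence OTUs always kept", {
  m <- rbind(s1 = c(1, 0, 2), s2 = c(1, 1, 2),
             s3 = c(1, 1, 2), s4 = c(1, 1, 2))
  colnames(m) <- c("allpresent", "onezero", "constant")
  res <- errthresh_filter(abundance_table(m, "counts"))
  expect_equal(res$report$threshold, 0.4)
  expect_equal(res$report$dropped_otu_ids, "onezero")
  expect_true(all(c("allpresent", "constant") %in% res$report$kept_otu_ids))
})

test_that("errthresh residual pool records the excluded relative mass", {
  m <- rbind(s1 = c(8, 0, 2), s2 = c(5, 0, 5),
             s3 = c(6, 2, 2), s4 = c(1, 0, 9))
  colnames(m) <- c("a", "rare", "b")
  rel <- to_relative(abundance_table(m, "counts"))
  res <- errthresh_filter(rel)
  expect_equal(res$report$dropped_otu_ids, "rare")
  pool <- res$report$residual_pool
  expect_equal(pool$residual, unname(abund_matrix(rel)[, "rare"]))
  expect_true(all(pool$residual >= 0 & pool$residual <= 1))
})
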