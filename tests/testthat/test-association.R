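test_that("similarity measures match their closed forms", {
  expect_equal(similarity(c(1, 2, 3), c(2, 4, 6), "pearson"), 1.0)
  # 1 - 6 * sum(d^2) / (n (n^2 - 1)) with sum(d^2) = 6, n = 3
  expect_equal(similarity(c(1, 2, 3), c(3, 1, 2), "spearman"), -0.5)
  # rank invariance under strictly increasing transforms
  set.seed(1)
  x <- runif(20); y <- runif(20)
  expect_equal(similarity(x, y, "spearman"),
               similarity(exp(3 * x), y^3 + 7, "spearman"),
               tolerance = 1e-12)
  expect_equal(similarity(x, exp(x), "spearman"), 1)
  # degenerate input is flagged, not an error
  expect_true(is.na(similarity(rep(2, 5), 1:5, "pearson")))
  expect_error(similarity(1:3, 1:4), "equal length")
  expect_error(similarity(1:2, 2:1), "at least 3")
})

test_that("noise injection follows gamma = s * x_min and vanishes at s = 0", {
  m <- rbind(s1 = c(2e-5, 0.3), s2 = c(0.5, 0.2), s3 = c(0.1, 0.4))
  colnames(m) <- c("a", "b")
  tab <- abundance_table(m, "relative")
  expect_equal(noise_gamma(tab, 10), 2e-4)
  expect_equal(noise_gamma(tab, "low"), 2e-5)
  expect_equal(noise_gamma(tab, "none"), 0)
  set.seed(7)
  x <- runif(10); y <- runif(10)
  expect_identical(noisy_similarity(x, y, "spearman", gamma = 0),
                   similarity(x, y, "spearman"))
})

test_that("noise breaks double-zero artefacts: null correlation for all-zero vectors", {
  set.seed(2)
  zeros <- rep(0, 30)
  draws <- replicate(1000,
                     noisy_similarity(zeros, zeros, "spearman", gamma = 1e-5))
  expect_lt(abs(mean(draws)), 0.1)
})

test_that("z-test matches its closed forms in both variants", {
  pooled <- zscore_test(0.8, 0.1, 0.0, 0.1, variant = "pooled")
  expect_equal(pooled$z, 0.8 / sqrt(0.02), tolerance = 1e-6)
  expect_equal(pooled$z, 5.657, tolerance = 1e-4)
  expect_equal(pooled$p, 1.54e-8, tolerance = 1e-2)
  perm <- zscore_test(0.8, 0.1, 0.0, 0.1, variant = "permutation")
  expect_equal(perm$z, 8)
  # identical distributions give z = 0, p = 1
  same <- zscore_test(0.4, 0.05, 0.4, 0.05)
  expect_equal(same$z, 0)
  expect_equal(same$p, 1)
  # sign(z) always follows sign(boot_mean - perm_mean)
  set.seed(3)
  bm <- runif(50, -1, 1); pm <- runif(50, -1, 1)
  zt <- zscore_test(bm, 0.1, pm, 0.1)
  expect_equal(sign(zt$z), sign(bm - pm))
  # degenerate denominator is flagged
  expect_true(is.na(zscore_test(0.5, 0, 0.1, 0)$z))
})

test_that("Benjamini-Yekutieli q-values match a brute-force oracle", {
  expect_equal(adjust_q(c(0.01, 0.02, 0.03)), rep(0.055, 3),
               tolerance = 1e-12)
  expect_equal(adjust_q(0.7), 0.7)  # c(1) = 1
  expect_equal(adjust_q(numeric(0)), numeric(0))
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(adjust_q(p), brute_force_by(p), tolerance = 1e-12)
  }
})

test_that("reboot flags a planted strong co-variation as significant", {
  set.seed(10)
  n <- 50
  base <- runif(n)
  m <- cbind(x = base + rnorm(n, 0, 0.05),
             y = base + rnorm(n, 0, 0.05),
             noise1 = runif(n), noise2 = runif(n))
  m <- m - min(m)  # keep abundances non-negative
  rownames(m) <- sprintf("s%02d", 1:n)
  stopifnot(cor(m[, "x"], m[, "y"], method = "spearman") > 0.9)
  res <- reboot(abundance_table(m, "counts"), s = 0, iterations = 1000,
                seed = 99)
  hit <- dplyr::filter(res, otu_a == "x", otu_b == "y")
  expect_gt(hit$z, 0)
  expect_lt(hit$q, 1e-3)
})

test_that("reboot is reproducible under a fixed seed and reports all pairs", {
  sim <- generate_experiment(small_config())
  rel <- to_relative(sim$counts)
  keep <- filter_by_max_abundance(rel, "low")$table
  r1 <- reboot(keep, s = "low", iterations = 100, seed = 5)
  r2 <- reboot(keep, s = "low", iterations = 100, seed = 5)
  expect_identical(r1, r2)
  p <- length(otu_ids(keep))
  expect_equal(nrow(r1), p * (p - 1) / 2)
  expect_true(all(r1$p >= 0 & r1$p <= 1))
  expect_true(all(r1$q <= 1))
})

test_that("permutation null of independent data is centred at zero", {
  set.seed(8)
  m <- matrix(runif(30 * 6), 30, 6,
              dimnames = list(sprintf("s%02d", 1:30), sprintf("o%d", 1:6)))
  res <- reboot(abundance_table(m, "counts"), s = 0, iterations = 400,
                seed = 21)
  expect_true(mean(abs(res$perm_mean) < 3 * res$perm_sd / sqrt(400)) > 0.5)
  expect_lt(max(abs(res$perm_mean)), 0.05)
})

test_that("renormalization is refused for non-relative abundances", {
  sim <- generate_experiment(small_config())
  expect_error(reboot(sim$counts, renormalize = TRUE, iterations = 100),
               "renormaliz")
  rel <- to_relative(sim$counts)
  abs_tab <- to_absolute(rel, sim$density)
  expect_error(reboot(abs_tab, renormalize = TRUE, iterations = 100),
               "renormaliz")
})

test_that("constant OTUs are excluded from the testing family", {
  m <- cbind(const = rep(4, 20),
             a = runif(20), b = runif(20))
  rownames(m) <- sprintf("s%02d", 1:20)
  res <- reboot(abundance_table(m, "counts"), s = 0, iterations = 100,
                seed = 2)
  expect_false(any(res$otu_a == "const" | res$otu_b == "const"))
  expect_equal(nrow(res), 1)
})
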