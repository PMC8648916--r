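# Shared fixtures built in code; kept tiny so the default run stays fast.

tiny_counts <- function() {
  m <- matrix(c(5, 1, 0,
                3, 0, 3,
                2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("OTU_1", "OTU_2", "OTU_3")))
  abundance_table(m, "counts")
}

small_config <- function(...) {
  simulation_config(n_k_otus = 8, n_r_otus = 8, n_neutral_otus = 2,
                    n_microcosms = 4,
                    days = c(1, 8, 16, 24, 28, 29, 36, 43, 50),
                    depth = 2000, seed = 11, ...)
}

# independent step-up Benjamini-Yekutieli oracle, written from the
# definition: q_(i) = min over j >= i of p_(j) * m * c(m) / j, capped at 1
brute_force_by <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  q_sorted <- p[o] * m * cm / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# hand ARI from the contingency-table formula, independent of mclust
ari_by_hand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  (sum_ij - expected) / (maxi - expected)
}

# edge tibble for two positive cliques (sizes na, nb) joined by one
# negative edge; z magnitudes descend so q ordering is deterministic
two_clique_edges <- function(na = 5, nb = 4) {
  a <- sprintf("A%02d", seq_len(na))
  b <- sprintf("B%02d", seq_len(nb))
  pairs <- function(v) t(combn(v, 2))
  pos <- rbind(pairs(a), pairs(b))
  edges <- tibble::tibble(
    otu_a = c(pos[, 1], a[1]),
    otu_b = c(pos[, 2], b[1]),
    similarity = c(rep(0.9, nrow(pos)), -0.9),
    z = c(rep(5, nrow(pos)), -5),
    p = 1e-8, q = 1e-6,
    sign = c(rep("+", nrow(pos)), "-"))
  edges
}
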