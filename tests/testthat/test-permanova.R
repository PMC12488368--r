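make_two_clusters <- function(sep = 10, n = 12, seed = 2) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n * 2, 0, 0.1), ncol = 2),
             matrix(rnorm(n * 2, sep, 0.1), ncol = 2))
  rownames(x) <- paste0("S", seq_len(2 * n))
  stats::dist(x)
}

test_that("PERMANOVA separates far clusters at the permutation floor", {
  # 12 samples per cluster: the chance that a random permutation happens to
  # preserve the cluster partition (tying the observed pseudo-F) is ~7e-7,
  # so the permutation p-value sits at its floor 1/(B+1)
  d <- make_two_clusters()
  labs <- rep(c("g1", "g2"), each = 12)
  fit <- permanova(d, labs, n_permutations = 999, seed = 1)
  expect_equal(fit$p_value, 1 / 1000, tolerance = 1e-12)
  expect_gt(fit$r_squared, 0.9)
  # reproducible given the seed; p never below 1/(B+1)
  expect_identical(fit$p_value,
                   permanova(d, labs, n_permutations = 999, seed = 1)$p_value)
  expect_gte(permanova(d, labs, n_permutations = 99, seed = 3)$p_value,
             1 / 100)
})

test_that("PERMANOVA rejects degenerate group structures", {
  d <- make_two_clusters()
  expect_error(permanova(d, rep("only", 24)), "two groups")
  expect_error(permanova(d, c(rep("a", 23), "b")), "fewer than 2")
})

test_that("pseudo-F matches a direct computation of the sum-of-squares decomposition", {
  d <- make_two_clusters(sep = 2, n = 4, seed = 9)
  labs <- rep(c("a", "b"), each = 4)
  fit <- permanova(d, labs, n_permutations = 99, seed = 1)
  dm <- as.matrix(d)^2
  n <- 8; g <- 2
  ss_total <- sum(dm[upper.tri(dm)]) / n
  ss_within <- 0
  for (lv in unique(labs)) {
    idx <- which(labs == lv)
    sub <- dm[idx, idx]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  f_oracle <- ((ss_total - ss_within) / (g - 1)) / (ss_within / (n - g))
  expect_equal(fit$pseudo_f, f_oracle, tolerance = 1e-9)
  expect_equal(fit$r_squared, (ss_total - ss_within) / ss_total,
               tolerance = 1e-9)
})

test_that("pairwise PERMANOVA applies BH within the requested contrast family", {
  # BH on (0.01, 0.02, 0.03) -> (0.03, 0.03, 0.03), checked via p.adjust
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))

  set.seed(4)
  x <- rbind(matrix(rnorm(12, 0, 0.3), ncol = 2),
             matrix(rnorm(12, 4, 0.3), ncol = 2),
             matrix(rnorm(12, c(0, 4), 0.3), ncol = 2))
  rownames(x) <- paste0("S", 1:18)
  d <- stats::dist(x)
  labs <- rep(c("a", "b", "c"), each = 6)
  res <- pairwise_permanova(d, labs, n_permutations = 199, seed = 1)
  expect_identical(nrow(res), 3L)
  expect_true(all(res$p_adjusted >= res$p_value))
  # adjusted values are non-decreasing in the order of raw p
  o <- order(res$p_value)
  expect_true(all(diff(res$p_adjusted[o]) >= -1e-12))
  # single contrast: adjusted equals raw
  one <- pairwise_permanova(d, labs, contrasts = list(c("a", "b")),
                            n_permutations = 199, seed = 1)
  expect_identical(one$p_adjusted, one$p_value)
  expect_error(pairwise_permanova(d, labs, contrasts = list()), "empty")
  expect_error(pairwise_permanova(d, labs, contrasts = list(c("a", "zz"))),
               "not present")
})

test_that("Wilcoxon rank-sum uses the exact branch and matches enumeration", {
  w <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12))
  expect_true(w$exact)
  expect_equal(w$p_value, 0.1, tolerance = 1e-12)
  expect_equal(w$p_value, oracle_wilcoxon_p(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-12)

  # identical multisets -> p = 1 (tie-corrected approximation branch)
  w2 <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_false(w2$exact)
  expect_equal(w2$p_value, 1, tolerance = 0.05)

  # all 3-vs-3 splits of distinct values match full enumeration exactly
  vals <- 1:6
  splits <- utils::combn(6, 3)
  for (k in seq_len(ncol(splits))) {
    a <- vals[splits[, k]]
    b <- vals[-splits[, k]]
    expect_equal(wilcoxon_rank_sum(a, b)$p_value, oracle_wilcoxon_p(a, b),
                 tolerance = 1e-12, label = paste(a, collapse = ","))
  }

  # exact and approximate branches agree for moderate n
  set.seed(10)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  pe <- wilcoxon_rank_sum(a, b)$p_value
  pa <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
  expect_lt(abs(pe - pa), 0.02)

  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})
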