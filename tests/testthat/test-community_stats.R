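test_that("low-abundance filter keeps exactly the ASVs at or above the cutoff", {
  m <- matrix(c(20L, 5L, 3L, 7L, 5L, 4L, 3L), 7, 1,
              dimnames = list(paste0("A", 1:7), "S1"))
  m <- cbind(m, S2 = c(5L, 4L, 7L, 0L, 0L, 0L, 1L))
  tab <- asv_table(m)
  tot <- rowSums(m)  # 25, 9, 10, 7, 5, 4, 4
  kept <- asv_counts(filter_low_abundance(tab, 10))
  expect_identical(rownames(kept), names(tot)[tot >= 10])  # 10 retained
  expect_identical(asv_counts(filter_low_abundance(tab, 0)), m)
  expect_error(filter_low_abundance(tab, 1000), "threshold")

  # oracle: independent row-sum recomputation on a random table
  rt <- random_table(50, 20, seed = 8)
  keep_oracle <- apply(asv_counts(rt), 1, sum) >= 10
  expect_identical(rownames(asv_counts(filter_low_abundance(rt, 10))),
                   rownames(asv_counts(rt))[keep_oracle])
})

test_that("alpha diversity matches closed forms", {
  m <- cbind(S1 = c(25L, 25L, 25L, 25L), S2 = c(7L, 0L, 0L, 0L),
             S3 = c(1L, 1L, 2L, 0L))
  rownames(m) <- paste0("A", 1:4)
  a <- alpha_diversity(asv_table(m))
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_identical(a$observed_richness[2], 1L)
  expect_equal(a$shannon[2], 0, tolerance = 1e-12)
  expect_equal(a$shannon[3], 1.039721, tolerance = 1e-6)
  m0 <- cbind(m, S4 = c(0L, 0L, 0L, 0L))
  expect_error(alpha_diversity(asv_table(m0)), "S4")
})

test_that("Bray-Curtis matches the hand formula and its invariants", {
  m <- cbind(S1 = c(2L, 2L, 0L), S2 = c(0L, 2L, 2L), S3 = c(2L, 2L, 0L),
             S4 = c(0L, 0L, 5L))
  rownames(m) <- paste0("A", 1:3)
  d <- as.matrix(bray_curtis(asv_table(m)))
  expect_equal(d["S1", "S2"], 0.5, tolerance = 1e-12)
  expect_equal(d["S1", "S3"], 0)                     # identical columns
  expect_equal(d["S1", "S4"], 1)                     # disjoint supports

  # property: symmetry, zero diagonal, [0,1] range, agreement with the
  # direct formula, over randomized tables
  for (s in 1:25) {
    rt <- random_table(15, 6, lambda = 2, seed = 100 + s)
    mm <- asv_counts(rt)
    mm[, colSums(mm) == 0] <- 1L                     # guard zero columns
    dd <- as.matrix(bray_curtis(asv_table(mm)))
    expect_equal(dd, t(dd), tolerance = 1e-12)
    expect_true(all(diag(dd) == 0))
    expect_true(all(dd >= 0 & dd <= 1))
    expect_equal(dd[1, 2], bray_hand(mm[, 1], mm[, 2]), tolerance = 1e-12)
    expect_equal(dd[3, 6], bray_hand(mm[, 3], mm[, 6]), tolerance = 1e-12)
  }
})

test_that("rank aggregation conserves totals and matches a group-and-sum oracle", {
  tab <- random_table(30, 8, seed = 12)
  tax <- data.frame(asv_id = rownames(asv_counts(tab)),
                    phylum = sample(c("Firmicutes", "Bacteroidota",
                                      "Proteobacteria", NA), 30,
                                    replace = TRUE),
                    genus = sample(letters[1:10], 30, replace = TRUE),
                    stringsAsFactors = FALSE)
  agg <- aggregate_by_rank(tab, tax, "phylum")
  expect_identical(colSums(asv_counts(agg)), colSums(asv_counts(tab)))
  lab <- ifelse(is.na(tax$phylum), "Unclassified", tax$phylum)
  oracle <- rowsum(asv_counts(tab), lab)
  expect_equal(asv_counts(agg)[rownames(oracle), ], oracle,
               ignore_attr = TRUE)
  # two ASVs of one phylum sum per sample
  two <- which(lab == lab[1])[1:2]
  if (length(two) == 2 && !any(is.na(two))) {
    expect_identical(asv_counts(agg)[lab[1], 1],
                     oracle[lab[1], 1])
  }
  expect_error(aggregate_by_rank(tab, tax, "family"), "unknown taxonomic rank")
})

test_that("PCoA reproduces closed forms and embeds Euclidean data exactly", {
  # two samples at distance d: one positive eigenvalue d^2/2, separation d
  d2 <- stats::as.dist(matrix(c(0, 0.6, 0.6, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  expect_warning(ord <- pcoa(d2, n_axes = 2), "truncating")
  expect_equal(max(ord$eigenvalues), 0.6^2 / 2, tolerance = 1e-12)
  expect_equal(abs(ord$points[1, 1] - ord$points[2, 1]), 0.6,
               tolerance = 1e-12)

  # three equidistant samples: two equal positive eigenvalues
  d3 <- stats::as.dist(matrix(0.4, 3, 3) - diag(0.4, 3))
  ord3 <- pcoa(d3, n_axes = 2)
  pos <- ord3$eigenvalues[ord3$eigenvalues > 1e-12]
  expect_equal(pos[1], pos[2], tolerance = 1e-12)

  # a Euclidean configuration is reproduced to 1e-9
  set.seed(3)
  x <- matrix(rnorm(40), 10, 4)
  de <- stats::dist(x)
  orde <- suppressWarnings(pcoa(de, n_axes = 9))
  expect_lt(max(abs(as.matrix(stats::dist(orde$points)) - as.matrix(de))),
            1e-9)
})

test_that("NMDS recovers a planted 2-D configuration and is seed-stable", {
  set.seed(6)
  x <- matrix(rnorm(30), 15, 2)
  d <- stats::dist(x)
  fit <- nmds(d, n_axes = 2, seed = 1)
  expect_lt(fit$stress, 0.01)
  fit2 <- nmds(d, n_axes = 2, seed = 1)
  expect_identical(fit$points, fit2$points)
  expect_identical(fit$stress, fit2$stress)
  expect_error(nmds(stats::as.dist(matrix(c(0, 1, 1, 0), 2)), n_axes = 2),
               "at least 3 samples")
})
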