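disjoint_sources <- function(n_pool = 20, depth = 1000) {
  ids <- sprintf("A%02d", seq_len(2 * n_pool))
  a <- c(rep(depth / n_pool, n_pool), rep(0, n_pool))
  b <- c(rep(0, n_pool), rep(depth / n_pool, n_pool))
  names(a) <- names(b) <- ids
  list(a = a, b = b, ids = ids)
}

test_that("disjoint-support mixtures are recovered exactly without smoothing", {
  s <- disjoint_sources()
  sink <- 0.7 * s$a + 0.3 * s$b
  est <- fit_source_proportions(sink, list(A = s$a, B = s$b),
                                include_unknown = FALSE, pseudocount = 0)
  # responsibilities are 0/1, so the closed form is exact
  expect_identical(unname(est$proportions), c(0.7, 0.3))
  expect_true(est$converged)
})

test_that("a single source with unknown disabled gets everything", {
  s <- disjoint_sources()
  est <- fit_source_proportions(s$a, list(only = s$a),
                                include_unknown = FALSE)
  expect_equal(unname(est$proportions), 1, tolerance = 1e-12)
})

test_that("sinks drawn from one source leave at most 5% elsewhere", {
  set.seed(9)
  n <- 120
  pa <- numeric(n); pa[1:60] <- dyadtrack:::rdirichlet1(rep(0.5, 60))
  pb <- numeric(n); pb[61:120] <- dyadtrack:::rdirichlet1(rep(0.5, 60))
  srcA <- rmultinom(1, 1e4, pa)[, 1]
  srcB <- rmultinom(1, 1e4, pb)[, 1]
  sink <- rmultinom(1, 1e4, pa)[, 1]
  est <- fit_source_proportions(sink, list(A = srcA, B = srcB))
  expect_gte(est$proportions[["A"]], 0.95)
})

test_that("the likelihood trace is monotone and proportions sum to one", {
  set.seed(19)
  for (r in 1:10) {
    n <- 90
    p1 <- dyadtrack:::rdirichlet1(rep(0.3, n))
    p2 <- dyadtrack:::rdirichlet1(rep(0.3, n))
    sink <- rmultinom(1, 5000, 0.6 * p1 + 0.4 * p2)[, 1]
    est <- fit_source_proportions(sink,
                                  list(x = rmultinom(1, 5000, p1)[, 1],
                                       y = rmultinom(1, 5000, p2)[, 1]))
    expect_true(all(diff(est$log_likelihood_trace) >= -1e-9))
    expect_equal(sum(est$proportions), 1, tolerance = 1e-9)
  }
})

test_that("permuting source order permutes the estimate identically", {
  set.seed(29)
  n <- 60
  p1 <- dyadtrack:::rdirichlet1(rep(0.4, n))
  p2 <- dyadtrack:::rdirichlet1(rep(0.4, n))
  s1 <- rmultinom(1, 4000, p1)[, 1]
  s2 <- rmultinom(1, 4000, p2)[, 1]
  sink <- rmultinom(1, 4000, 0.7 * p1 + 0.3 * p2)[, 1]
  e12 <- fit_source_proportions(sink, list(first = s1, second = s2))
  e21 <- fit_source_proportions(sink, list(second = s2, first = s1))
  expect_equal(e12$proportions[c("first", "second")],
               e21$proportions[c("first", "second")], tolerance = 1e-12)
  expect_equal(e12$proportions[["unknown"]], e21$proportions[["unknown"]],
               tolerance = 1e-12)
})

test_that("input validation catches mismatched or empty communities", {
  s <- disjoint_sources()
  expect_error(fit_source_proportions(s$a[1:10], list(A = s$a)), "length")
  expect_error(fit_source_proportions(0 * s$a, list(A = s$a)), "zero total")
  expect_error(fit_source_proportions(s$a, list(A = 0 * s$a)), "zero total")
  # reads outside the sources' support need the unknown (or smoothing)
  expect_error(fit_source_proportions(s$a + s$b, list(A = s$a),
                                      include_unknown = FALSE,
                                      pseudocount = 0),
               "unknown source")
})

test_that("cohort source tracking skips incomplete dyads and sums to one", {
  co <- simulate_cohort(simulation_params(
    n_gdm_dyads = 5, n_control_dyads = 3, n_asvs = 80, env_pool_size = 20,
    depth = 3000, n_gdm_no_t2 = 2, seed = 61))
  tab <- filter_low_abundance(co$table)
  dy <- build_dyads(co$metadata, tab)
  expect_message(st <- track_cohort_sources(dy, tab), "skipping 2")
  expect_identical(nrow(st), 6L)
  expect_equal(st$mother + st$meconium + st$unknown, rep(1, 6),
               tolerance = 1e-9)
})

test_that("a T2 identical to its meconium is attributed to the meconium source", {
  set.seed(71)
  n <- 100
  pm <- numeric(n); pm[1:50] <- dyadtrack:::rdirichlet1(rep(0.4, 50))
  pt <- numeric(n); pt[41:100] <- dyadtrack:::rdirichlet1(rep(0.4, 60))
  mother <- rmultinom(1, 1e4, pm)[, 1]
  t1 <- rmultinom(1, 1e4, pt)[, 1]
  est <- fit_source_proportions(t1, list(mother = mother, meconium = t1))
  expect_gte(est$proportions[["meconium"]], 0.95)
  expect_lte(est$proportions[["unknown"]], 0.05)
})

test_that("a mother-dominated T2 admixture yields mother > meconium on average", {
  co <- simulate_cohort(simulation_params(
    n_gdm_dyads = 8, n_control_dyads = 4, t2_mother_weight = 0.9, rho = 0.3,
    seed = 5))
  tab <- filter_low_abundance(co$table)
  st <- track_cohort_sources(build_dyads(co$metadata, tab), tab)
  expect_gt(mean(st$mother), mean(st$meconium))
})
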