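#' PERMANOVA on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance for a single grouping
#' factor (one-way), computed via [vegan::adonis2]. The pseudo-F statistic
#' compares between- to within-group squared dissimilarity; the p-value is
#' \eqn{(1 + \#\{F_{perm} \ge F_{obs}\}) / (1 + B)} under unrestricted
#' label permutation and is therefore never below \eqn{1/(B+1)}.
#'
#' @param d A [stats::dist] object.
#' @param labels Group label per sample, in the order of `d`'s labels.
#' @param n_permutations Number of permutations B (default 999).
#' @param seed Integer seed; results are reproducible given it.
#' @return A list of class `permanova_result` with `pseudo_f`, `r_squared`,
#'   `p_value`, `df`, `n_permutations`, `groups`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = 1) {
  if (!inherits(d, "dist")) stopf("d must be a 'dist' object")
  n <- attr(d, "Size")
  labels <- as.character(labels)
  if (length(labels) != n) stopf("labels length (%d) != number of samples (%d)",
                                 length(labels), n)
  tab <- table(labels)
  if (length(tab) < 2) stopf("need at least two groups, got: %s",
                             toString(names(tab)))
  small <- names(tab)[tab < 2]
  if (length(small)) stopf("group(s) with fewer than 2 samples: %s",
                           toString(small))
  dat <- data.frame(group = factor(labels))
  set.seed(seed)
  fit <- vegan::adonis2(d ~ group, data = dat, permutations = n_permutations)
  structure(list(pseudo_f = fit$F[1],
                 r_squared = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1],
                 df = c(between = fit$Df[1], within = fit$Df[2]),
                 n_permutations = n_permutations,
                 groups = names(tab)),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.3f, R2 = %.3f, p = %.4g (B = %d)\n",
              paste(x$groups, collapse = " vs "), x$pseudo_f, x$r_squared,
              x$p_value, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA with FDR adjustment
#'
#' Runs [permanova()] on the sample subset of each requested pair of groups
#' and adjusts the permutation p-values by Benjamini-Hochberg across the
#' contrast list (the adjustment family is this call's contrasts, not the
#' whole study).
#'
#' @param d A [stats::dist] object.
#' @param labels Group label per sample, in the order of `d`'s labels.
#' @param contrasts List of 2-vectors of group labels; `NULL` means all
#'   pairs of observed groups.
#' @param n_permutations,seed Passed to [permanova()]; each contrast is run
#'   with its own derived seed for standalone reproducibility.
#' @return A data frame of class `pairwise_permanova` with one row per
#'   contrast: `group_a`, `group_b`, `n_a`, `n_b`, `pseudo_f`, `r_squared`,
#'   `p_value`, `p_adjusted`, `n_permutations`.
#' @export
pairwise_permanova <- function(d, labels, contrasts = NULL,
                               n_permutations = 999, seed = 1) {
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (is.null(contrasts)) {
    if (length(lev) < 2) stopf("need at least two groups")
    contrasts <- utils::combn(lev, 2, simplify = FALSE)
  }
  if (!length(contrasts)) stopf("empty contrast list")
  dm <- as.matrix(d)
  rows <- lapply(seq_along(contrasts), function(k) {
    ct <- contrasts[[k]]
    if (length(ct) != 2) stopf("each contrast must name exactly two groups")
    missing_g <- setdiff(ct, lev)
    if (length(missing_g)) stopf("contrast group(s) not present: %s",
                                 toString(missing_g))
    idx <- which(labels %in% ct)
    sub <- stats::as.dist(dm[idx, idx])
    fit <- permanova(sub, labels[idx], n_permutations = n_permutations,
                     seed = seed + k)
    data.frame(group_a = ct[1], group_b = ct[2],
               n_a = sum(labels == ct[1]), n_b = sum(labels == ct[2]),
               pseudo_f = fit$pseudo_f, r_squared = fit$r_squared,
               p_value = fit$p_value, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$n_permutations <- n_permutations
  class(res) <- c("pairwise_permanova", "data.frame")
  res
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon test used for alpha-diversity and
#' relative-abundance comparisons. Uses the exact null distribution when
#' the smaller group has at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie correction and continuity
#' correction.
#'
#' @param values_a,values_b Numeric vectors, both non-empty.
#' @return A list with `statistic` (W), `p_value`, and `exact` (logical:
#'   which branch was used).
#' @export
wilcoxon_rank_sum <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) {
    stopf("both groups must be non-empty")
  }
  if (length(values_a) + length(values_b) < 2) stopf("need at least 2 values")
  ties <- any(duplicated(c(values_a, values_b)))
  exact <- min(length(values_a), length(values_b)) <= 8 && !ties
  ht <- suppressWarnings(stats::wilcox.test(values_a, values_b,
                                            alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, exact = exact)
}
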