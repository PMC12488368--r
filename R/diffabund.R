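#' Median-of-ratios size factors
#'
#' DESeq-style library-size normalization: the reference abundance of each
#' ASV is its geometric mean across samples (over ASVs positive in every
#' sample), and a sample's size factor is the median across ASVs of its
#' counts divided by the reference. Meconium tables are often too sparse to
#' contain any ubiquitous ASV; in that case a positive-counts fallback is
#' used (geometric means computed over positive counts only, medians over
#' each sample's positive ASVs, factors rescaled to geometric mean 1).
#'
#' @param x An [asv_table].
#' @param fallback If `TRUE` (default), fall back to the positive-counts
#'   estimator when no ASV is positive in all samples; if `FALSE`, error.
#' @return Named numeric vector of positive per-sample size factors.
#' @export
estimate_size_factors <- function(x, fallback = TRUE) {
  m <- asv_counts(x)
  ubi <- rowSums(m > 0) == ncol(m)
  if (any(ubi)) {
    lm_ref <- rowMeans(log(m[ubi, , drop = FALSE]))
    # median taken on the log scale (geometric interpolation at even n),
    # matching the canonical median-of-ratios estimator
    sf <- apply(m[ubi, , drop = FALSE], 2, function(cnt) {
      exp(stats::median(log(cnt) - lm_ref))
    })
  } else {
    if (!fallback) {
      stopf("no ASV has positive counts in every sample; enable fallback")
    }
    lg <- log(m); lg[!is.finite(lg)] <- 0
    lm_ref <- rowSums(lg) / ncol(m)          # poscounts-style geometric mean
    sf <- vapply(seq_len(ncol(m)), function(j) {
      pos <- m[, j] > 0
      if (!any(pos)) stopf("sample '%s' has no positive counts", colnames(m)[j])
      exp(stats::median(log(m[pos, j]) - lm_ref[pos]))
    }, numeric(1))
    sf <- sf / exp(mean(log(sf)))
    names(sf) <- colnames(m)
  }
  if (any(!is.finite(sf) | sf <= 0)) stopf("non-positive size factor estimated")
  sf
}

#' Negative-binomial Wald differential abundance
#'
#' A DESeq2-style two-group Wald test without the shrinkage machinery:
#' counts are normalized by median-of-ratios size factors; a per-ASV
#' dispersion is estimated by method of moments on normalized counts
#' (floored at 1e-8); the log2 fold change is the log-ratio of group means
#' (with a 0.5 pseudocount replacing a zero group mean); its standard error
#' comes from the delta method under NB variance \eqn{\mu + \alpha\mu^2};
#' the Wald statistic is referred to the standard normal and p-values are
#' Benjamini-Hochberg adjusted across tested ASVs. Dispersion and fold
#' change are deliberately unshrunk: the stage is validated by parameter
#' recovery on synthetic cohorts, not coefficient equality with DESeq2.
#'
#' @param x An [asv_table].
#' @param condition Factor-like vector of length `ncol(x)` with exactly two
#'   levels, each represented by at least two samples. Fold changes are
#'   reported for the second level relative to the first (levels in sorted
#'   order unless `condition` is a factor).
#' @param fallback Passed to [estimate_size_factors()].
#' @return A data frame of class `differential_result` with one row per
#'   tested ASV: `asv_id`, `base_mean`, `log2_fold_change`, `lfc_se`,
#'   `wald_statistic`, `p_value`, `p_adjusted`. ASVs with all-zero counts
#'   are excluded (with a message).
#' @export
nb_wald_test <- function(x, condition, fallback = TRUE) {
  m <- asv_counts(x)
  if (length(condition) != ncol(m)) {
    stopf("condition length (%d) != number of samples (%d)",
          length(condition), ncol(m))
  }
  f <- if (is.factor(condition)) droplevels(condition) else factor(condition)
  if (nlevels(f) != 2) {
    stopf("condition must have exactly two levels, got %d (%s)",
          nlevels(f), toString(levels(f)))
  }
  if (any(table(f) < 2)) {
    stopf("each condition level needs at least 2 samples")
  }
  lev <- levels(f)
  allzero <- rowSums(m) == 0
  if (any(allzero)) {
    message(sprintf("excluding %d all-zero ASV(s) from testing", sum(allzero)))
    m <- m[!allzero, , drop = FALSE]
  }
  sf <- estimate_size_factors(asv_table(m), fallback = fallback)
  q <- sweep(m, 2, sf, "/")                     # normalized counts
  ia <- which(f == lev[1]); ib <- which(f == lev[2])
  na <- length(ia); nb <- length(ib)
  mu_a <- rowMeans(q[, ia, drop = FALSE])
  mu_b <- rowMeans(q[, ib, drop = FALSE])
  va <- apply(q[, ia, drop = FALSE], 1, stats::var)
  vb <- apply(q[, ib, drop = FALSE], 1, stats::var)

  # method-of-moments dispersion, pooled across groups, floored
  mom <- function(mu, v) ifelse(mu > 0, (v - mu) / mu^2, NA_real_)
  aa <- mom(mu_a, va); ab <- mom(mu_b, vb)
  disp <- rowMeans(cbind(aa, ab), na.rm = TRUE)
  disp[is.nan(disp) | is.na(disp)] <- 0
  disp <- pmax(disp, 1e-8)

  mu_a_eff <- ifelse(mu_a > 0, mu_a, 0.5)
  mu_b_eff <- ifelse(mu_b > 0, mu_b, 0.5)
  lfc <- log2(mu_b_eff / mu_a_eff)

  # delta method: Var(log2 mu_hat_g) ~ Var(mu_hat_g) / (mu_g ln 2)^2, with
  # Var(mu_hat_g) = (1/n_g^2) sum_j (mu_g / s_j + disp * mu_g^2)
  inv_sa <- sum(1 / sf[ia]); inv_sb <- sum(1 / sf[ib])
  var_mu_a <- (mu_a_eff * inv_sa + na * disp * mu_a_eff^2) / na^2
  var_mu_b <- (mu_b_eff * inv_sb + nb * disp * mu_b_eff^2) / nb^2
  se <- sqrt(var_mu_a / mu_a_eff^2 + var_mu_b / mu_b_eff^2) / log(2)
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  res <- data.frame(asv_id = rownames(m), base_mean = rowMeans(q),
                    log2_fold_change = lfc, lfc_se = se,
                    wald_statistic = z, p_value = p,
                    p_adjusted = stats::p.adjust(p, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "contrast") <- c(reference = lev[1], test = lev[2])
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Select group-enriched marker ASVs
#'
#' Applies the marker rule: an ASV is a marker when its log2 fold change
#' strictly exceeds `lfc_min` and its BH-adjusted p-value is strictly below
#' `alpha`. Defaults (3.5, 0.001) are the stringent maternal GDM-marker
#' thresholds; the infant-contrast screening threshold of adjusted p < 0.01
#' can be obtained by setting `alpha = 0.01` (and `lfc_min = 0`).
#'
#' @param result A [nb_wald_test()] result.
#' @param lfc_min Minimum log2 fold change (strict).
#' @param alpha Maximum adjusted p-value (strict).
#' @return A data frame of class `marker_set` (subset of `result` rows,
#'   sorted by decreasing fold change) with the thresholds recorded as
#'   attributes `lfc_min` and `alpha`.
#' @export
select_markers <- function(result, lfc_min = 3.5, alpha = 0.001) {
  if (!all(c("log2_fold_change", "p_adjusted") %in% names(result))) {
    stopf("result must be a differential_result data frame")
  }
  sel <- result$log2_fold_change > lfc_min & result$p_adjusted < alpha
  out <- result[sel, , drop = FALSE]
  out <- out[order(-out$log2_fold_change, out$asv_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lfc_min") <- lfc_min
  attr(out, "alpha") <- alpha
  class(out) <- c("marker_set", "data.frame")
  out
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("Marker set: %d ASVs (log2FC > %g, adjusted p < %g)\n",
              nrow(x), attr(x, "lfc_min"), attr(x, "alpha")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... (%d more)\n", nrow(x) - 10))
  invisible(x)
}
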