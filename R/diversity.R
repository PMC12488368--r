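#' Remove low-abundance ASVs
#'
#' Drops ASVs whose cumulative count across all samples is below
#' `min_total` (strictly below: an ASV totalling exactly `min_total` is
#' retained). This mirrors the pre-filter applied before vertical-transfer
#' and source-tracking analyses.
#'
#' @param x An [asv_table].
#' @param min_total Minimum cumulative count across samples (default 10).
#' @return A filtered [asv_table] with the same samples.
#' @export
filter_low_abundance <- function(x, min_total = 10) {
  m <- asv_counts(x)
  keep <- rowSums(m) >= min_total
  if (!any(keep)) {
    stopf("all ASVs fall below min_total = %g; review the threshold", min_total)
  }
  asv_table(m[keep, , drop = FALSE])
}

#' Per-sample alpha diversity
#'
#' Observed richness (number of ASVs with positive count) and the Shannon
#' index, \eqn{H = -\sum_i p_i \ln p_i} with natural logarithm over the
#' sample's relative abundances (zero terms skipped).
#'
#' @param x An [asv_table]; every sample must have a positive total.
#' @return A data frame with columns `sample_id`, `observed_richness`,
#'   `shannon`.
#' @export
alpha_diversity <- function(x) {
  m <- asv_counts(x)
  tot <- colSums(m)
  if (any(tot == 0)) {
    stopf("sample(s) with zero total count: %s",
          toString(colnames(m)[tot == 0]))
  }
  shannon <- vapply(seq_len(ncol(m)), function(j) {
    p <- m[, j] / tot[j]
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
  data.frame(sample_id = colnames(m),
             observed_richness = as.integer(colSums(m > 0)),
             shannon = shannon,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' Computes pairwise Bray-Curtis dissimilarity between samples on raw
#' counts, \eqn{d(a,b) = 1 - 2\sum_i \min(a_i, b_i) / (\sum_i a_i + \sum_i
#' b_i)}. No rarefaction is applied by default; optional rarefaction to the
#' minimum sample depth is exposed for sensitivity analysis.
#'
#' @param x An [asv_table] with at least two samples, all totals positive.
#' @param rarefy If `TRUE`, subsample every sample without replacement to
#'   the minimum sample total before computing distances.
#' @param seed Seed used only when `rarefy = TRUE`.
#' @return A [stats::dist] object labelled by sample id.
#' @export
bray_curtis <- function(x, rarefy = FALSE, seed = 1) {
  m <- asv_counts(x)
  if (ncol(m) < 2) stopf("need at least two samples")
  tot <- colSums(m)
  if (any(tot == 0)) {
    stopf("sample(s) with zero total count: %s",
          toString(colnames(m)[tot == 0]))
  }
  if (rarefy) {
    set.seed(seed)
    m <- t(vegan::rrarefy(t(m), min(tot)))
  }
  vegan::vegdist(t(m), method = "bray")
}

#' Aggregate an ASV table at a taxonomic rank
#'
#' Sums counts over ASVs sharing the same label at the requested rank.
#' ASVs missing from the taxonomy, or unassigned at that rank, are pooled
#' into an `"Unclassified"` bucket, so column totals are preserved exactly.
#'
#' @param x An [asv_table].
#' @param taxonomy A taxonomy data frame (see [read_taxonomy()]).
#' @param rank Name of a rank column in `taxonomy` (e.g. `"phylum"`).
#' @return An [asv_table] whose features are taxa at the requested rank.
#' @export
aggregate_by_rank <- function(x, taxonomy, rank) {
  m <- asv_counts(x)
  if (!rank %in% setdiff(names(taxonomy), "asv_id")) {
    stopf("unknown taxonomic rank '%s'; available: %s", rank,
          toString(setdiff(names(taxonomy), "asv_id")))
  }
  lab <- taxonomy[[rank]][match(rownames(m), taxonomy$asv_id)]
  lab <- as.character(lab)
  lab[is.na(lab) | lab == ""] <- "Unclassified"
  agg <- rowsum(m, group = lab)
  asv_table(agg[order(rownames(agg)), , drop = FALSE])
}
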