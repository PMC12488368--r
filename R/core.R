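#' Core microbiome of a sample group
#'
#' Identifies ASVs whose prevalence (fraction of the subset's samples in
#' which they are detected) strictly exceeds `prevalence_min`. Detection is
#' any positive count by default. With the default 0.90 threshold a group
#' of 16 samples requires presence in at least 15 of them (15/16 = 0.9375
#' is the smallest fraction above 0.90).
#'
#' @param x An [asv_table].
#' @param sample_subset Character vector of sample ids defining the group
#'   (e.g. vaginally delivered GDM mothers); must be non-empty columns of
#'   `x`.
#' @param prevalence_min Strict prevalence threshold (default 0.90).
#' @param detection Count strictly above which an ASV is "present"
#'   (default 0).
#' @return A data frame of class `core_set` with columns `asv_id`,
#'   `prevalence`, sorted by decreasing prevalence then id; thresholds kept
#'   as attributes.
#' @export
core_microbiome <- function(x, sample_subset, prevalence_min = 0.90,
                            detection = 0) {
  m <- asv_counts(x)
  if (!length(sample_subset)) stopf("sample_subset is empty")
  missing_s <- setdiff(sample_subset, colnames(m))
  if (length(missing_s)) stopf("sample(s) not in table: %s", toString(missing_s))
  sub <- m[, sample_subset, drop = FALSE]
  prev <- rowMeans(sub > detection)
  keep <- prev > prevalence_min
  out <- data.frame(asv_id = rownames(m)[keep], prevalence = prev[keep],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence, out$asv_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "prevalence_min") <- prevalence_min
  attr(out, "detection") <- detection
  attr(out, "n_samples") <- length(sample_subset)
  class(out) <- c("core_set", "data.frame")
  out
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf("Core microbiome: %d ASVs with prevalence > %g over %d samples\n",
              nrow(x), attr(x, "prevalence_min"), attr(x, "n_samples")))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... (%d more)\n", nrow(x) - 10))
  invisible(x)
}

#' Track an ASV set across samples
#'
#' Returns the relative abundances of a fixed ASV set (e.g. a maternal core
#' or marker set) in a set of samples, for heatmap-style follow-up of the
#' set in infant communities. ASVs absent from every requested sample are
#' kept as explicit zero rows: absence is part of the tracking result.
#'
#' @param asv_set Character vector of ASV ids (non-empty).
#' @param x An [asv_table].
#' @param sample_subset Sample ids (columns of `x`); defaults to all.
#' @return Numeric matrix `length(asv_set)` x `length(sample_subset)` of
#'   relative abundances (each column of `x` normalized by its total).
#' @export
track_set_in_samples <- function(asv_set, x, sample_subset = NULL) {
  if (!length(asv_set)) stopf("asv_set is empty")
  m <- asv_counts(x)
  sample_subset <- sample_subset %||% colnames(m)
  missing_s <- setdiff(sample_subset, colnames(m))
  if (length(missing_s)) stopf("sample(s) not in table: %s", toString(missing_s))
  rel <- sweep(m[, sample_subset, drop = FALSE], 2,
               colSums(m[, sample_subset, drop = FALSE]), "/")
  out <- matrix(0, length(asv_set), length(sample_subset),
                dimnames = list(asv_set, sample_subset))
  hit <- intersect(asv_set, rownames(m))
  out[hit, ] <- rel[hit, , drop = FALSE]
  out
}

#' Ward-linkage row ordering for heatmaps
#'
#' Leaf order of an agglomerative hierarchical clustering of the rows
#' (Euclidean distance, Ward linkage as implemented by `ward.D2`), as used
#' to order core/marker heatmaps. Deterministic: `hclust` merges are
#' tie-broken by original index order.
#'
#' @param m Numeric matrix with at least one row.
#' @return Integer permutation of `1:nrow(m)`; a single row returns `1`.
#' @export
ward_cluster_order <- function(m) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (nrow(m) < 1) stopf("matrix has no rows")
  if (nrow(m) == 1) return(1L)
  stats::hclust(stats::dist(m, method = "euclidean"),
                method = "ward.D2")$order
}
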