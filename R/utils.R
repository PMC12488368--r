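# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @keywords internal
#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Deterministic per-stage seed expansion: one user-facing seed drives every
# stochastic stage via seed + 97 * stage_index (mod 2^31 - 2, kept >= 1).
# Documented in the methods vignette; stable across runs and platforms.
stage_seed <- function(seed, stage) {
  stages <- c(
    simulate = 1L, filter = 2L, diversity = 3L, ordinate = 4L,
    permanova = 5L, diffabund = 6L, core = 7L, transmit = 8L,
    sourcetrack = 9L
  )
  if (!stage %in% names(stages)) stopf("unknown pipeline stage '%s'", stage)
  as.integer((as.numeric(seed) + 97 * stages[[stage]]) %% 2147483645 + 1)
}

# presence of an ASV means a strictly positive count
presence_ids <- function(x, sample_id) {
  counts <- asv_counts(x)
  if (!sample_id %in% colnames(counts)) {
    stopf("sample '%s' not found in the count table", sample_id)
  }
  rownames(counts)[counts[, sample_id] > 0]
}

# draw from a Dirichlet distribution via independent gammas
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1  # degenerate underflow guard
  g / sum(g)
}
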