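#' ASV count table
#'
#' Construct and validate a feature-by-sample table of amplicon sequence
#' variant (ASV) read counts. Features (ASVs) are rows and samples are
#' columns, the orientation used by QIIME-style feature tables; this is the
#' single canonical orientation used throughout the package.
#'
#' @param counts A numeric matrix of non-negative integer read counts with
#'   unique ASV identifiers as row names and unique sample identifiers as
#'   column names.
#' @param lenient If `TRUE`, non-integer counts are floored with a warning
#'   instead of raising an error. Downstream models (multinomial resampling,
#'   negative-binomial tests) assume true counts, so the default is strict.
#'
#' @return An object of class `asv_table`: an integer matrix with ASV row
#'   names and sample column names.
#'
#' @examples
#' m <- matrix(c(3L, 1L, 0L, 7L), 2, 2,
#'             dimnames = list(c("A", "B"), c("S1", "S2")))
#' asv_table(m)
#' @export
asv_table <- function(counts, lenient = FALSE) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stopf("an ASV table needs at least one feature and one sample")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stopf("ASV table requires ASV row names and sample column names")
  }
  dup_r <- unique(rownames(counts)[duplicated(rownames(counts))])
  if (length(dup_r)) stopf("duplicate ASV id(s): %s", toString(dup_r))
  dup_c <- unique(colnames(counts)[duplicated(colnames(counts))])
  if (length(dup_c)) stopf("duplicate sample id(s): %s", toString(dup_c))
  if (!is.numeric(counts)) stopf("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stopf("negative or non-finite count at ASV '%s', sample '%s'",
          rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]])
  }
  frac <- which(counts != floor(counts), arr.ind = TRUE)
  if (nrow(frac)) {
    if (lenient) {
      warnf("%d non-integer count(s) floored (lenient mode)", nrow(frac))
      counts <- floor(counts)
    } else {
      stopf("non-integer count at ASV '%s', sample '%s' (use lenient = TRUE to floor)",
            rownames(counts)[frac[1, 1]], colnames(counts)[frac[1, 2]])
    }
  }
  storage.mode(counts) <- "integer"
  structure(counts, class = c("asv_table", "matrix", "array"))
}

#' Extract the count matrix from an ASV table
#'
#' @param x An `asv_table` (or plain matrix, returned as-is).
#' @return An integer matrix, features as rows, samples as columns.
#' @export
asv_counts <- function(x) {
  if (inherits(x, "asv_table")) {
    m <- unclass(x)
  } else if (is.matrix(x)) {
    m <- x
  } else {
    stopf("expected an asv_table or matrix")
  }
  m
}

#' @export
print.asv_table <- function(x, ...) {
  m <- asv_counts(x)
  cat(sprintf("ASV count table: %d ASVs x %d samples, %s reads total\n",
              nrow(m), ncol(m), format(sum(as.numeric(m)), big.mark = ",")))
  k <- min(5L, nrow(m)); j <- min(5L, ncol(m))
  print(m[seq_len(k), seq_len(j), drop = FALSE])
  if (nrow(m) > k || ncol(m) > j) {
    cat(sprintf("... (%d more ASVs, %d more samples)\n",
                nrow(m) - k, ncol(m) - j))
  }
  invisible(x)
}

#' @export
`[.asv_table` <- function(x, i, j, ..., drop = FALSE) {
  m <- asv_counts(x)[i, j, ..., drop = drop]
  if (is.matrix(m) && nrow(m) >= 1 && ncol(m) >= 1) asv_table(m) else m
}

#' @export
summary.asv_table <- function(object, ...) {
  m <- asv_counts(object)
  cat(sprintf("ASV count table: %d ASVs x %d samples\n", nrow(m), ncol(m)))
  cat("Reads per sample:\n")
  print(summary(colSums(m)))
  cat("Nonzero ASVs per sample:\n")
  print(summary(colSums(m > 0)))
  invisible(object)
}
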