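#' Principal coordinates analysis (PCoA)
#'
#' Classical metric scaling of a dissimilarity matrix: Gower double
#' centering of \eqn{-d^2/2} followed by eigendecomposition. Axes are
#' ordered by decreasing eigenvalue; axes with non-positive eigenvalues
#' carry no metric information and are dropped, with the negative
#' eigenvalues reported for diagnostics (no correction is applied).
#'
#' @param d A [stats::dist] object (e.g. from [bray_curtis()]).
#' @param n_axes Number of axes requested; truncated with a warning when it
#'   exceeds the number of positive eigenvalues.
#' @return A list of class `ordination` with `points` (samples x axes),
#'   `eigenvalues` (all of them, decreasing), `negative_eigenvalues`, and
#'   `method = "PCoA"`.
#' @export
pcoa <- function(d, n_axes = 2) {
  if (!inherits(d, "dist")) stopf("d must be a 'dist' object")
  n <- attr(d, "Size")
  if (n < 2) stopf("need at least two samples")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  n_pos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (n_axes > n_pos) {
    warnf("requested %d axes but only %d have positive eigenvalues; truncating",
          n_axes, n_pos)
    n_axes <- n_pos
  }
  pts <- fit$points[, seq_len(n_axes), drop = FALSE]
  colnames(pts) <- paste0("PCo", seq_len(n_axes))
  rownames(pts) <- attr(d, "Labels") %||% rownames(fit$points)
  structure(list(points = pts,
                 eigenvalues = sort(eig, decreasing = TRUE),
                 negative_eigenvalues = sort(eig[eig < 0]),
                 method = "PCoA"),
            class = "ordination")
}

#' Non-metric multidimensional scaling (NMDS)
#'
#' Minimizes Kruskal stress-1 by iterative improvement from a PCoA starting
#' configuration (via [vegan::monoMDS], global monotone regression).
#' Deterministic given the seed. Non-convergence within `max_iter` is
#' flagged on the result, not raised as an error.
#'
#' @param d A [stats::dist] object.
#' @param n_axes Number of ordination axes (default 2); requires at least
#'   `n_axes + 1` samples.
#' @param seed Integer seed (start-configuration jitter reproducibility).
#' @param max_iter Maximum number of stress-minimization iterations.
#' @return A list of class `ordination` with `points`, `stress` (stress-1,
#'   fraction in `[0, 1]`), `converged` and `method = "NMDS"`.
#' @export
nmds <- function(d, n_axes = 2, seed = 1, max_iter = 500) {
  if (!inherits(d, "dist")) stopf("d must be a 'dist' object")
  n <- attr(d, "Size")
  if (n < n_axes + 1) {
    stopf("NMDS with %d axes needs at least %d samples, got %d",
          n_axes, n_axes + 1, n)
  }
  set.seed(seed)
  start <- suppressWarnings(stats::cmdscale(d, k = n_axes))
  if (ncol(start) < n_axes) {
    start <- cbind(start, matrix(stats::rnorm(n * (n_axes - ncol(start)),
                                              sd = 1e-4), n))
  }
  fit <- vegan::monoMDS(d, y = start, k = n_axes, model = "global",
                        maxit = max_iter)
  pts <- fit$points
  colnames(pts) <- paste0("NMDS", seq_len(n_axes))
  rownames(pts) <- attr(d, "Labels")
  structure(list(points = pts,
                 stress = fit$stress,
                 converged = fit$icause != 1L,  # 1 = iteration limit hit
                 iterations = fit$iters,
                 method = "NMDS"),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d axes\n",
              x$method, nrow(x$points), ncol(x$points)))
  if (x$method == "PCoA") {
    pos <- x$eigenvalues[x$eigenvalues > 0]
    expl <- pos[seq_len(min(ncol(x$points), length(pos)))] / sum(pos)
    cat(sprintf("  variance explained: %s\n",
                paste(sprintf("%.1f%%", 100 * expl), collapse = ", ")))
    if (length(x$negative_eigenvalues)) {
      cat(sprintf("  %d negative eigenvalues (min %.3g) dropped\n",
                  length(x$negative_eigenvalues),
                  min(x$negative_eigenvalues)))
    }
  } else {
    cat(sprintf("  stress-1 = %.4f (%s)\n", x$stress,
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  }
  invisible(x)
}
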