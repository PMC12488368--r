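#' Microbial source tracking by expectation-maximization
#'
#' Estimates the mixing proportions of a sink community over a set of
#' known source communities plus an optional unknown source. The sink's
#' counts are modelled as multinomial over the mixture
#' \eqn{\sum_k \alpha_k \gamma_k}, with known-source distributions
#' \eqn{\gamma_k} fixed plug-ins (source relative abundances smoothed by a
#' pseudocount per ASV). The E-step computes responsibilities
#' \eqn{r_{ik} = \alpha_k \gamma_{ki} / \sum_l \alpha_l \gamma_{li}}; the
#' M-step sets \eqn{\alpha_k = \sum_i y_i r_{ik} / \sum_i y_i}. With the
#' component distributions fixed the log-likelihood is concave in
#' \eqn{\alpha}, so the fit is deterministic and globally convergent from
#' the uniform start.
#'
#' The unknown source's composition is estimated once, between two EM
#' passes: the mixture is first fit over the known sources alone, and the
#' unknown distribution is set to the positive part of the sink's residual
#' (observed minus fitted relative abundance) exceeding a two-standard-
#' deviation multinomial sampling allowance, so that pure sampling noise
#' is not attributed to the unknown. If no residual survives the
#' allowance, the unknown proportion is reported as 0. A freely re-fit
#' unknown distribution is not used because it makes the empirical sink
#' distribution the global optimum (the unknown alone can explain every
#' read), collapsing the estimate to `unknown = 1` regardless of the
#' sources. The log-likelihood trace of the final pass is non-decreasing
#' (asserted internally). Fixing the known sources is a deliberate
#' simplification relative to full joint re-estimation; the stage is
#' validated by mixture recovery on simulated sinks.
#'
#' @param sink_counts Named integer vector of sink counts (positive total).
#' @param sources Named list of source count vectors on the same ASV axis,
#'   or a matrix with sources as columns; each source total must be
#'   positive.
#' @param include_unknown Include an unknown source component (default
#'   `TRUE`).
#' @param pseudocount Smoothing pseudocount added to every ASV of each
#'   known source before normalization (default 1). Set to 0 for exact
#'   closed-form behaviour on sources that fully cover the sink support.
#' @param max_iter Maximum EM iterations per pass (default 1000).
#' @param tol Absolute log-likelihood gain below which EM stops (default
#'   1e-8).
#' @param restarts Number of additional random-initialization restarts of
#'   the final pass (default 0; with fixed component distributions the
#'   likelihood is concave in the proportions, so restarts are a
#'   safety net, not a necessity).
#' @param seed Seed used only when `restarts > 0`.
#' @return An object of class `source_estimate`: list with `proportions`
#'   (named, includes `unknown` when enabled, sums to 1), `log_likelihood`,
#'   `log_likelihood_trace` (final pass), `iterations` (total over both
#'   passes), `converged`, and `unknown_distribution` (or `NULL`).
#' @examples
#' a <- c(A1 = 500L, A2 = 500L, B1 = 0L, B2 = 0L)
#' b <- c(A1 = 0L, A2 = 0L, B1 = 500L, B2 = 500L)
#' sink <- c(A1 = 350L, A2 = 350L, B1 = 150L, B2 = 150L)
#' fit_source_proportions(sink, list(a = a, b = b),
#'                        include_unknown = FALSE, pseudocount = 0)
#' @export
fit_source_proportions <- function(sink_counts, sources,
                                   include_unknown = TRUE, pseudocount = 1,
                                   max_iter = 1000, tol = 1e-8,
                                   restarts = 0, seed = 1) {
  y <- as.numeric(sink_counts)
  if (is.matrix(sources)) {
    sources <- stats::setNames(
      lapply(seq_len(ncol(sources)), function(j) sources[, j]),
      colnames(sources) %||% paste0("source", seq_len(ncol(sources))))
  }
  if (!length(sources)) stopf("need at least one source")
  if (is.null(names(sources)) || any(!nzchar(names(sources)))) {
    names(sources) <- paste0("source", seq_along(sources))
  }
  n <- length(y)
  for (nm in names(sources)) {
    if (length(sources[[nm]]) != n) {
      stopf("source '%s' length (%d) != sink length (%d)", nm,
            length(sources[[nm]]), n)
    }
    if (sum(sources[[nm]]) <= 0) stopf("source '%s' has zero total", nm)
  }
  if (sum(y) <= 0) stopf("sink has zero total count")
  if (any(y < 0)) stopf("negative sink counts")

  gamma_known <- vapply(sources, function(s) {
    s <- as.numeric(s) + pseudocount
    s / sum(s)
  }, numeric(n))                                 # n x K_known
  support <- which(y > 0)
  y_pos <- y[support]
  n_reads <- sum(y_pos)
  phat <- y_pos / n_reads
  gk <- gamma_known[support, , drop = FALSE]
  k_known <- ncol(gk)

  # EM over proportions with fixed component columns G (rows sum > 0)
  em_alpha <- function(alpha, G, yv) {
    trace <- numeric(0)
    ll_old <- -Inf
    converged <- FALSE
    iter <- 0L
    repeat {
      iter <- iter + 1L
      mix <- as.vector(G %*% alpha)
      ll <- sum(yv * log(mix))
      trace <- c(trace, ll)
      if (ll < ll_old - 1e-9) {
        stopf("internal error: EM log-likelihood decreased (%.12g -> %.12g)",
              ll_old, ll)
      }
      if (iter > 1 && ll - ll_old < tol) { converged <- TRUE; break }
      if (iter >= max_iter) break
      ll_old <- ll
      R <- sweep(G, 2, alpha, "*") / mix
      w <- colSums(yv * R)
      alpha <- w / sum(w)
    }
    list(alpha = alpha, trace = trace, iterations = iter,
         converged = converged, mix = as.vector(G %*% alpha))
  }

  covered <- rowSums(gk) > 0
  if (!include_unknown && !all(covered)) {
    stopf(paste("sink has reads on ASVs with zero source probability;",
                "enable the unknown source or use a positive pseudocount"))
  }

  # pass 1: known sources only, on the covered part of the sink
  cov_mass <- sum(phat[covered])
  fit1 <- em_alpha(rep(1 / k_known, k_known), gk[covered, , drop = FALSE],
                   y_pos[covered])
  if (!include_unknown) {
    props <- fit1$alpha
    names(props) <- names(sources)
    stopifnot(abs(sum(props) - 1) < 1e-9)
    return(structure(list(proportions = props,
                          log_likelihood = fit1$trace[length(fit1$trace)],
                          log_likelihood_trace = fit1$trace,
                          iterations = fit1$iterations,
                          converged = fit1$converged,
                          unknown_distribution = NULL),
                     class = "source_estimate"))
  }

  # unknown composition: positive residual beyond sampling allowance
  mix_full <- numeric(length(y_pos))
  mix_full[covered] <- cov_mass * fit1$mix
  resid <- pmax(phat - mix_full - 2 * sqrt(mix_full / n_reads), 0)
  if (sum(resid) == 0) {
    props <- c(fit1$alpha, 0)
    names(props) <- c(names(sources), "unknown")
    gamma_u_full <- numeric(n)
    return(structure(list(proportions = props,
                          log_likelihood = fit1$trace[length(fit1$trace)],
                          log_likelihood_trace = fit1$trace,
                          iterations = fit1$iterations,
                          converged = fit1$converged,
                          unknown_distribution = gamma_u_full),
                     class = "source_estimate"))
  }
  gamma_u <- resid / sum(resid)
  G <- cbind(gk, gamma_u)

  # pass 2: full mixture including the unknown component
  k_all <- k_known + 1L
  fits <- list(em_alpha(rep(1 / k_all, k_all), G, y_pos))
  if (restarts > 0) {
    set.seed(seed)
    for (r in seq_len(restarts)) {
      fits[[r + 1]] <- em_alpha(rdirichlet1(rep(1, k_all)), G, y_pos)
    }
  }
  lls <- vapply(fits, function(f) f$trace[length(f$trace)], numeric(1))
  best <- fits[[which.max(lls)]]
  props <- best$alpha
  names(props) <- c(names(sources), "unknown")
  stopifnot(abs(sum(props) - 1) < 1e-9)
  gamma_u_full <- numeric(n)
  gamma_u_full[support] <- gamma_u
  structure(list(proportions = props,
                 log_likelihood = best$trace[length(best$trace)],
                 log_likelihood_trace = best$trace,
                 iterations = fit1$iterations + best$iterations,
                 converged = fit1$converged && best$converged,
                 unknown_distribution = gamma_u_full),
            class = "source_estimate")
}

#' @export
print.source_estimate <- function(x, ...) {
  cat("Source proportions (EM):\n")
  print(round(x$proportions, 4))
  cat(sprintf("  log-likelihood %.4f after %d iterations (%s)\n",
              x$log_likelihood, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Source tracking across a dyad cohort
#'
#' Fits [fit_source_proportions()] for every complete dyad's 6-week (T2)
#' stool, with the dyad's maternal sample and meconium (T1) as the known
#' sources and an unknown component for everything else. Incomplete dyads
#' are skipped with a message.
#'
#' @param dyads A [build_dyads()] result.
#' @param x The low-abundance-filtered [asv_table].
#' @param ... Passed to [fit_source_proportions()].
#' @return A data frame of class `source_tracking` with one row per fitted
#'   dyad: `dyad_id`, `group`, `mother`, `meconium`, `unknown`,
#'   `log_likelihood`, `iterations`, `converged`.
#' @export
track_cohort_sources <- function(dyads, x, ...) {
  dy <- as.data.frame(dyads)
  skip <- is.na(dy$t1) | is.na(dy$t2) | is.na(dy$mother)
  if (any(skip)) {
    message(sprintf("skipping %d incomplete dyad(s): %s", sum(skip),
                    toString(dy$dyad_id[skip])))
    dy <- dy[!skip, , drop = FALSE]
  }
  if (!nrow(dy)) stopf("no complete dyads to source-track")
  m <- asv_counts(x)
  rows <- lapply(seq_len(nrow(dy)), function(i) {
    d <- dy[i, ]
    est <- fit_source_proportions(
      m[, d$t2],
      list(mother = m[, d$mother], meconium = m[, d$t1]), ...)
    p <- est$proportions
    data.frame(dyad_id = d$dyad_id, group = d$group,
               mother = unname(p["mother"]), meconium = unname(p["meconium"]),
               unknown = if ("unknown" %in% names(p)) unname(p["unknown"]) else 0,
               log_likelihood = est$log_likelihood,
               iterations = est$iterations, converged = est$converged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("source_tracking", "data.frame")
  out
}
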