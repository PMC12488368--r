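# Per-dyad vertical-transmission bookkeeping.
#
# All operations work on presence/absence (count > 0) in a low-abundance-
# filtered table, and track exact ASV identity between a dyad's maternal,
# meconium (T1) and 6-week (T2) samples. Percentages with an empty
# denominator are undefined and propagate as NA, never as 0.

dyad_row <- function(dyad) {
  if (is.data.frame(dyad)) {
    if (nrow(dyad) != 1) stopf("expected a single dyad row")
    as.list(dyad)
  } else if (is.list(dyad)) {
    dyad
  } else {
    stopf("dyad must be a dyad_set row or a list with mother/t1/t2 ids")
  }
}

#' Shared and unique meconium ASVs of one dyad
#'
#' Partitions the ASVs present in a dyad's meconium (T1) sample into those
#' also present in the paired maternal sample (shared, i.e. candidate
#' vertically transferred) and those absent from the mother (unique to the
#' infant). The shared percentage is taken over the T1-present total.
#'
#' @param dyad One row of a [build_dyads()] result (or a list with at least
#'   `mother` and `t1` sample ids).
#' @param x The low-abundance-filtered [asv_table].
#' @return List with `shared`, `unique` (character vectors of ASV ids) and
#'   `pct_shared_t1` (`NA` when the T1 sample has no present ASVs).
#' @export
shared_unique_t1 <- function(dyad, x) {
  d <- dyad_row(dyad)
  if (is.null(d$mother) || is.na(d$mother) || is.null(d$t1) || is.na(d$t1)) {
    stopf("dyad must have both mother and T1 samples")
  }
  mother_present <- presence_ids(x, d$mother)
  t1_present <- presence_ids(x, d$t1)
  shared <- intersect(t1_present, mother_present)
  uniq <- setdiff(t1_present, mother_present)
  pct <- if (length(t1_present)) 100 * length(shared) / length(t1_present) else NA_real_
  list(shared = shared, unique = uniq, pct_shared_t1 = pct)
}

#' Retention of shared ASVs from meconium to 6 weeks
#'
#' The transferred set is the part of the dyad's shared meconium ASVs still
#' present in its T2 (6-week) sample; the retention percentage is the
#' transferred count divided by the shared count times 100.
#'
#' @param dyad One dyad row (must have a T2 sample).
#' @param shared_set Shared ASV ids from [shared_unique_t1()].
#' @param x The filtered [asv_table].
#' @return List with `transferred` (ASV ids) and `pct_retained` (`NA` when
#'   the shared set is empty).
#' @export
retention_t1_to_t2 <- function(dyad, shared_set, x) {
  d <- dyad_row(dyad)
  if (is.null(d$t2) || is.na(d$t2)) stopf("dyad has no T2 sample")
  t2_present <- presence_ids(x, d$t2)
  transferred <- intersect(shared_set, t2_present)
  pct <- if (length(shared_set)) 100 * length(transferred) / length(shared_set) else NA_real_
  list(transferred = transferred, pct_retained = pct)
}

#' Contribution of transferred ASVs to the 6-week community
#'
#' The transferred count divided by the total number of ASVs present in
#' the dyad's T2 sample, times 100.
#'
#' @param dyad One dyad row (must have a T2 sample).
#' @param transferred_set Transferred ASV ids from [retention_t1_to_t2()].
#' @param x The filtered [asv_table].
#' @return `pct_contribution_t2` (`NA` when the T2 sample has no present
#'   ASVs).
#' @export
contribution_to_t2 <- function(dyad, transferred_set, x) {
  d <- dyad_row(dyad)
  if (is.null(d$t2) || is.na(d$t2)) stopf("dyad has no T2 sample")
  t2_present <- presence_ids(x, d$t2)
  if (!length(t2_present)) return(NA_real_)
  100 * length(transferred_set) / length(t2_present)
}

#' Cohort-level vertical-transmission records
#'
#' Computes one transmission record per eligible dyad (shared/unique
#' counts, retention and contribution percentages, and - when a marker set
#' is supplied - how many shared and transferred ASVs are GDM markers),
#' plus per-group summaries.
#'
#' @param dyads A [build_dyads()] result.
#' @param x The low-abundance-filtered [asv_table].
#' @param markers Optional character vector of marker ASV ids (or a
#'   `marker_set` data frame).
#' @param complete_pairs_only Restrict to dyads with mother, T1 and T2
#'   samples (default `TRUE`, matching the paired analysis design).
#' @param vaginal_only Restrict to dyads whose maternal `delivery_mode` is
#'   `"vaginal"`.
#' @return An object of class `transmission_records`: a list with
#'   `records` (data frame, one row per dyad) and `summary` (per-group
#'   min/mean/max of each percentage over defined records, with n).
#' @export
cohort_transmission <- function(dyads, x, markers = NULL,
                                complete_pairs_only = TRUE,
                                vaginal_only = FALSE) {
  dy <- as.data.frame(dyads)
  if (inherits(markers, "data.frame")) markers <- markers$asv_id
  if (vaginal_only) {
    dy <- dy[!is.na(dy$delivery_mode) & dy$delivery_mode == "vaginal", ,
             drop = FALSE]
  }
  dy <- dy[!is.na(dy$t1), , drop = FALSE]
  if (complete_pairs_only) dy <- dy[!is.na(dy$t2), , drop = FALSE]
  if (!nrow(dy)) stopf("no eligible dyads after filtering")

  rows <- lapply(seq_len(nrow(dy)), function(i) {
    d <- dy[i, ]
    su <- shared_unique_t1(d, x)
    n_t1 <- length(su$shared) + length(su$unique)
    has_t2 <- !is.na(d$t2)
    if (has_t2) {
      ret <- retention_t1_to_t2(d, su$shared, x)
      n_t2 <- length(presence_ids(x, d$t2))
      pct_contrib <- if (n_t2) 100 * length(ret$transferred) / n_t2 else NA_real_
      n_transferred <- length(ret$transferred)
      pct_ret <- ret$pct_retained
      n_marker_t2 <- if (!is.null(markers)) length(intersect(ret$transferred, markers)) else NA_integer_
    } else {
      n_t2 <- NA_integer_; n_transferred <- NA_integer_
      pct_ret <- NA_real_; pct_contrib <- NA_real_
      n_marker_t2 <- NA_integer_
    }
    n_marker_t1 <- if (!is.null(markers)) length(intersect(su$shared, markers)) else NA_integer_
    data.frame(
      dyad_id = d$dyad_id, group = d$group,
      n_t1 = n_t1, n_shared_t1 = length(su$shared),
      n_unique_t1 = length(su$unique), pct_shared_t1 = su$pct_shared_t1,
      n_transferred = n_transferred, pct_retained = pct_ret,
      n_t2 = n_t2, pct_contribution_t2 = pct_contrib,
      n_marker_shared_t1 = n_marker_t1,
      pct_marker_t1 = if (!is.null(markers) && n_t1 > 0) 100 * n_marker_t1 / n_t1 else NA_real_,
      n_marker_transferred_t2 = n_marker_t2,
      pct_marker_t2 = if (!is.null(markers) && has_t2 && !is.na(n_t2) && n_t2 > 0)
        100 * n_marker_t2 / n_t2 else NA_real_,
      stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  stopifnot(all(records$n_shared_t1 + records$n_unique_t1 == records$n_t1))

  pct_cols <- c("pct_shared_t1", "pct_retained", "pct_contribution_t2",
                "pct_marker_t1", "pct_marker_t2")
  summ <- do.call(rbind, lapply(split(records, records$group), function(g) {
    do.call(rbind, lapply(pct_cols, function(col) {
      v <- g[[col]][!is.na(g[[col]])]
      data.frame(group = g$group[1], metric = col, n = length(v),
                 min = if (length(v)) min(v) else NA_real_,
                 mean = if (length(v)) mean(v) else NA_real_,
                 max = if (length(v)) max(v) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(summ) <- NULL
  structure(list(records = records, summary = summ,
                 markers = markers,
                 filters = list(complete_pairs_only = complete_pairs_only,
                                vaginal_only = vaginal_only)),
            class = "transmission_records")
}

#' @export
print.transmission_records <- function(x, ...) {
  r <- x$records
  cat(sprintf("Vertical transmission records: %d dyads (%d GDM, %d control)\n",
              nrow(r), sum(r$group == "GDM"), sum(r$group == "control")))
  s <- x$summary[x$summary$metric %in%
                   c("pct_shared_t1", "pct_retained", "pct_contribution_t2") &
                   x$summary$n > 0, ]
  if (nrow(s)) {
    cat("Per-group percentage summaries (over dyads with defined values):\n")
    print.data.frame(s, digits = 4, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.transmission_records <- function(object, ...) {
  object$summary
}

#' Marker-sharing frequency across dyads
#'
#' For each marker ASV, counts how many dyads carry it in their shared
#' meconium set (present in both mother and T1), i.e. how often the marker
#' is vertically transferred across the cohort.
#'
#' @param dyads A [build_dyads()] result (dyads without T1 are ignored).
#' @param markers Character vector of marker ASV ids (or a `marker_set`).
#' @param x The filtered [asv_table].
#' @return Data frame `asv_id`, `n_dyads_shared`, sorted by decreasing
#'   count then ASV id; markers shared by no dyad are reported with 0.
#' @export
marker_sharing_frequency <- function(dyads, markers, x) {
  if (inherits(markers, "data.frame")) markers <- markers$asv_id
  if (!length(markers)) stopf("markers is empty")
  dy <- as.data.frame(dyads)
  dy <- dy[!is.na(dy$t1) & !is.na(dy$mother), , drop = FALSE]
  counts <- stats::setNames(integer(length(markers)), markers)
  for (i in seq_len(nrow(dy))) {
    shared <- shared_unique_t1(dy[i, ], x)$shared
    hit <- intersect(markers, shared)
    counts[hit] <- counts[hit] + 1L
  }
  out <- data.frame(asv_id = names(counts), n_dyads_shared = unname(counts),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_dyads_shared, out$asv_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
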