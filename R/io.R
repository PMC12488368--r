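#' Read an ASV count table
#'
#' Reads a feature table from a tab-separated file (first column `asv_id`,
#' remaining columns one per sample) or a BIOM-style JSON file with
#' `"rows"`, `"columns"` and `"data"` keys (dense, or sparse triplets when
#' `"matrix_type": "sparse"`).
#'
#' @param path Path to the input file.
#' @param format Either `"tsv"` or `"biom-json"`.
#' @param transpose If `TRUE` the file stores samples as rows and ASVs as
#'   columns; it is transposed into the canonical features-as-rows
#'   orientation on read.
#' @param lenient Passed to [asv_table()]: floor non-integer counts with a
#'   warning instead of erroring.
#' @return An [asv_table].
#' @seealso [write_asv_table()]
#' @export
read_asv_table <- function(path, format = c("tsv", "biom-json"),
                           transpose = FALSE, lenient = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "tsv") {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            check.names = FALSE, comment.char = "",
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stopf("ASV table '%s' has no sample columns", path)
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- ids
    hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]][-1]
    dup <- unique(hdr[duplicated(hdr)])
    if (length(dup)) stopf("duplicate sample id(s) in header: %s", toString(dup))
    colnames(m) <- hdr
  } else {
    b <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    need <- c("rows", "columns", "data")
    miss <- setdiff(need, names(b))
    if (length(miss)) stopf("BIOM JSON missing key(s): %s", toString(miss))
    rid <- if (is.data.frame(b$rows)) as.character(b$rows$id) else as.character(b$rows)
    cid <- if (is.data.frame(b$columns)) as.character(b$columns$id) else as.character(b$columns)
    mt <- b$matrix_type %||% "dense"
    dat <- b$data
    if (is.list(dat)) dat <- do.call(rbind, lapply(dat, as.numeric))
    if (identical(mt, "sparse")) {
      m <- matrix(0, length(rid), length(cid))
      if (length(dat)) {
        # 0-based [row, col, value] triplets
        m[cbind(dat[, 1] + 1, dat[, 2] + 1)] <- dat[, 3]
      }
    } else {
      if (is.null(dat) || !length(dat)) stopf("BIOM JSON 'data' is empty")
      m <- dat
    }
    rownames(m) <- rid
    colnames(m) <- cid
  }
  if (transpose) m <- t(m)
  asv_table(m, lenient = lenient)
}

#' Write an ASV count table
#'
#' Writers always emit the canonical orientation: features as rows, samples
#' as columns. `read_asv_table(write_asv_table(x, p), p)` is the identity.
#'
#' @param x An [asv_table].
#' @param path Output path.
#' @param format `"tsv"` or `"biom-json"` (dense BIOM-style JSON).
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(x, path, format = c("tsv", "biom-json")) {
  format <- match.arg(format)
  m <- asv_counts(x)
  if (format == "tsv") {
    df <- data.frame(asv_id = rownames(m), m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    obj <- list(
      id = "asv-table", format = "dyadtrack BIOM-style JSON",
      matrix_type = "dense",
      shape = c(nrow(m), ncol(m)),
      rows = lapply(rownames(m), function(i) list(id = i, metadata = NULL)),
      columns = lapply(colnames(m), function(j) list(id = j, metadata = NULL)),
      data = lapply(seq_len(nrow(m)), function(i) unname(m[i, ]))
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(path)
}

.REQUIRED_META <- c("sample_id", "dyad_id", "group", "role", "timepoint")

#' Read dyad sample metadata
#'
#' Reads a tab-separated metadata file with required columns `sample_id`,
#' `dyad_id`, `group` (GDM or control), `role` (mother or infant) and
#' `timepoint` (antenatal for mothers; T1 = meconium or T2 = 6-week stool
#' for infants). Any additional columns (e.g. `delivery_mode`, `feeding`,
#' `antibiotics`) are retained as covariates.
#'
#' @param path Path to the TSV file.
#' @return A data frame of validated sample records, input order preserved.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate dyad sample metadata
#'
#' Checks the invariants of the sample record table: required columns
#' present, unique sample ids, known role/timepoint levels, and the
#' role-timepoint consistency rule (mothers are antenatal samples; infant
#' samples are T1 or T2).
#'
#' @param df A data frame of sample records.
#' @return The validated data frame (character columns, order preserved).
#' @export
validate_metadata <- function(df) {
  miss <- setdiff(.REQUIRED_META, names(df))
  if (length(miss)) stopf("metadata missing required column(s): %s", toString(miss))
  for (col in .REQUIRED_META) df[[col]] <- as.character(df[[col]])
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup)) stopf("duplicate sample id(s) in metadata: %s", toString(dup))
  bad_group <- setdiff(unique(df$group), c("GDM", "control"))
  if (length(bad_group)) stopf("unknown group label(s): %s", toString(bad_group))
  bad_role <- setdiff(unique(df$role), c("mother", "infant"))
  if (length(bad_role)) stopf("unknown role(s): %s", toString(bad_role))
  bad_tp <- setdiff(unique(df$timepoint), c("antenatal", "T1", "T2"))
  if (length(bad_tp)) stopf("unknown timepoint(s): %s", toString(bad_tp))
  viol <- (df$role == "mother" & df$timepoint != "antenatal") |
          (df$role == "infant" & !df$timepoint %in% c("T1", "T2"))
  if (any(viol)) {
    r <- df[which(viol)[1], ]
    stopf("illegal role/timepoint combination for sample '%s': role=%s, timepoint=%s",
          r$sample_id, r$role, r$timepoint)
  }
  df
}

#' Write dyad sample metadata
#' @param df A metadata data frame (see [read_metadata()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV with first column `asv_id` followed by rank columns ordered coarse to
#' fine (e.g. domain, phylum, class, order, family, genus). Unassigned cells
#' may be empty or NA.
#'
#' @param path Path to the TSV file.
#' @return A data frame with unique `asv_id` plus rank columns.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (names(df)[1] != "asv_id") stopf("taxonomy first column must be 'asv_id'")
  dup <- unique(df$asv_id[duplicated(df$asv_id)])
  if (length(dup)) stopf("duplicate ASV id(s) in taxonomy: %s", toString(dup))
  df
}

#' Assemble mother-infant dyads from sample metadata
#'
#' Links each dyad's maternal (antenatal), meconium (T1) and optional
#' 6-week (T2) samples. Dyads lacking a maternal sample are excluded with a
#' warning (no transmission analysis is possible for them). Absent T1/T2
#' samples are recorded as `NA` slots, never as empty communities.
#'
#' @param metadata A validated metadata data frame (see [read_metadata()]).
#' @param table Optional [asv_table]; when given, every metadata sample must
#'   be a column of the table.
#' @param complete_only If `TRUE`, keep only dyads with all three samples
#'   (mother, T1 and T2).
#' @return A data frame of class `dyad_set` with columns `dyad_id`, `group`,
#'   `mother`, `t1`, `t2`, and `delivery_mode` (from the maternal record
#'   when available, else `NA`).
#' @export
build_dyads <- function(metadata, table = NULL, complete_only = FALSE) {
  metadata <- validate_metadata(metadata)
  if (!is.null(table)) {
    missing_ids <- setdiff(metadata$sample_id, colnames(asv_counts(table)))
    if (length(missing_ids)) {
      stopf("metadata sample(s) absent from the count table: %s",
            toString(missing_ids))
    }
  }
  slot_of <- ifelse(metadata$role == "mother", "mother",
                    ifelse(metadata$timepoint == "T1", "t1", "t2"))
  rows <- lapply(split(seq_len(nrow(metadata)), metadata$dyad_id), function(idx) {
    d <- metadata[idx, ]
    did <- d$dyad_id[1]
    if (length(unique(d$group)) != 1L) {
      stopf("dyad '%s' has inconsistent group labels", did)
    }
    sl <- slot_of[idx]
    for (s in c("mother", "t1", "t2")) {
      if (sum(sl == s) > 1L) {
        stopf("dyad '%s' has %d '%s' samples; expected at most one",
              did, sum(sl == s), s)
      }
    }
    pick <- function(s) if (any(sl == s)) d$sample_id[sl == s] else NA_character_
    dm <- if ("delivery_mode" %in% names(d) && any(sl == "mother")) {
      as.character(d$delivery_mode[sl == "mother"])
    } else NA_character_
    data.frame(dyad_id = did, group = d$group[1], mother = pick("mother"),
               t1 = pick("t1"), t2 = pick("t2"), delivery_mode = dm,
               stringsAsFactors = FALSE)
  })
  dy <- do.call(rbind, rows)
  rownames(dy) <- NULL
  no_mother <- is.na(dy$mother)
  if (any(no_mother)) {
    warnf("excluding %d dyad(s) without a maternal sample: %s",
          sum(no_mother), toString(dy$dyad_id[no_mother]))
    dy <- dy[!no_mother, , drop = FALSE]
  }
  if (complete_only) dy <- dy[!is.na(dy$t1) & !is.na(dy$t2), , drop = FALSE]
  dy <- dy[order(dy$dyad_id), , drop = FALSE]
  rownames(dy) <- NULL
  class(dy) <- c("dyad_set", "data.frame")
  dy
}

#' @export
print.dyad_set <- function(x, ...) {
  cat(sprintf("Dyad set: %d dyads (%d GDM, %d control); %d with T1, %d complete (mother+T1+T2)\n",
              nrow(x), sum(x$group == "GDM"), sum(x$group == "control"),
              sum(!is.na(x$t1)), sum(!is.na(x$t1) & !is.na(x$t2))))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... (%d more dyads)\n", nrow(x) - 10))
  invisible(x)
}
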