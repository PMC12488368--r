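.CONFIG_TEMPLATE <- list(
  input = list(table = NA_character_, metadata = NA_character_,
               format = "tsv", taxonomy = NA_character_),
  simulate = list(),                 # simulation_params() arguments
  filter = list(min_total = 10),
  permanova = list(n_permutations = 999),
  markers = list(lfc_min = 3.5, alpha = 0.001),
  core = list(prevalence = 0.90, detection = 0),
  transmission = list(complete_pairs_only = TRUE, vaginal_only = TRUE),
  sourcetrack = list(include_unknown = TRUE, pseudocount = 1,
                     max_iter = 1000, tol = 1e-8),
  seed = 1,
  outdir = "dyadtrack-results"
)

#' Build and validate a pipeline configuration
#'
#' Merges user settings over the package defaults and validates them.
#' Unknown keys (at either level) are errors, not silently ignored. Either
#' an `input` block (paths to a count table and metadata TSV) or a
#' `simulate` block ([simulation_params()] arguments) must be supplied.
#'
#' @param config A nested list, or a path to a YAML file holding one.
#' @param ... Top-level overrides (e.g. `seed = 7`, `outdir = "out"`).
#' @return A validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), ...) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stopf("config must be a list or a YAML path")
  dots <- list(...)
  for (nm in names(dots)) config[[nm]] <- dots[[nm]]
  unknown <- setdiff(names(config), names(.CONFIG_TEMPLATE))
  if (length(unknown)) stopf("unknown config key(s): %s", toString(unknown))
  cfg <- .CONFIG_TEMPLATE
  for (nm in names(config)) {
    if (is.list(cfg[[nm]]) && nm != "simulate") {
      sub_unknown <- setdiff(names(config[[nm]]), names(cfg[[nm]]))
      if (length(sub_unknown)) {
        stopf("unknown config key(s) under '%s': %s", nm, toString(sub_unknown))
      }
      for (k in names(config[[nm]])) cfg[[nm]][[k]] <- config[[nm]][[k]]
    } else {
      cfg[[nm]] <- config[[nm]]
    }
  }
  has_input <- !is.na(cfg$input$table) && !is.na(cfg$input$metadata)
  has_sim <- "simulate" %in% names(config)
  if (!has_input && !has_sim) {
    stopf("config needs either input paths or a simulate block")
  }
  if (cfg$filter$min_total < 0) stopf("filter.min_total must be >= 0")
  if (cfg$markers$alpha <= 0 || cfg$markers$alpha > 1) {
    stopf("markers.alpha must lie in (0, 1]")
  }
  if (cfg$markers$lfc_min < 0) stopf("markers.lfc_min must be >= 0")
  if (cfg$core$prevalence <= 0 || cfg$core$prevalence >= 1) {
    stopf("core.prevalence must lie in (0, 1)")
  }
  if (cfg$permanova$n_permutations < 1) {
    stopf("permanova.n_permutations must be >= 1")
  }
  cfg$seed <- as.integer(cfg$seed)
  if (is.na(cfg$seed)) stopf("seed must be an integer")
  if (has_sim) {
    cfg$simulate <- do.call(simulation_params,
                            c(cfg$simulate,
                              if (!"seed" %in% names(cfg$simulate))
                                list(seed = stage_seed(cfg$seed, "simulate"))))
  }
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full dyad-cohort analysis pipeline
#'
#' Executes, in order: load or simulate the cohort; low-abundance filter;
#' alpha diversity and Bray-Curtis ordination; pairwise PERMANOVA between
#' sample classes (mothers/T1/T2 by group); maternal differential abundance
#' and GDM-marker selection; per-group maternal core microbiome and its
#' tracking in infants; per-dyad vertical-transmission records; and EM
#' source tracking of every complete dyad's T2 sample. All outputs are TSV
#' plus one JSON run summary recording every file, seed and threshold.
#' Every stochastic stage derives its own seed from the single config seed,
#' so reruns with the same config are byte-identical.
#'
#' @param config A [pipeline_config()] (or anything accepted by it).
#' @param outdir Output directory override.
#' @return Invisibly, a list with the in-memory stage results and
#'   `summary` (the run-summary list written as JSON).
#' @export
run_pipeline <- function(config = list(), outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  out <- function(name) {
    p <- file.path(cfg$outdir, name)
    files <<- c(files, p)
    p
  }
  stage <- "load"
  res <- list(config = cfg)
  tryCatch({
    # -- load or simulate ---------------------------------------------------
    if (length(cfg$simulate)) {
      cohort <- simulate_cohort(cfg$simulate)
      tab <- cohort$table
      metadata <- cohort$metadata
      res$truth <- cohort$truth
      write_asv_table(tab, out("asv_table.tsv"))
      write_metadata(metadata, out("metadata.tsv"))
      tr <- cohort$truth; tr$params <- unclass(tr$params)
      jsonlite::write_json(tr, out("truth.json"), auto_unbox = TRUE,
                           digits = NA, dataframe = "columns")
    } else {
      tab <- read_asv_table(cfg$input$table, format = cfg$input$format)
      metadata <- read_metadata(cfg$input$metadata)
    }
    dyads <- build_dyads(metadata, tab)
    res$dyads <- dyads

    stage <- "filter"
    filtered <- filter_low_abundance(tab, min_total = cfg$filter$min_total)
    res$filtered <- filtered
    write_asv_table(filtered, out("asv_table_filtered.tsv"))

    # sample-class labels: mother/T1/T2 crossed with group
    cls <- paste(ifelse(metadata$role == "mother", "mother",
                        metadata$timepoint), metadata$group, sep = ".")
    names(cls) <- metadata$sample_id

    stage <- "diversity"
    alpha <- alpha_diversity(filtered)
    alpha$class <- cls[alpha$sample_id]
    res$alpha <- alpha
    write_tsv(alpha, out("alpha_diversity.tsv"))
    d <- bray_curtis(filtered)
    res$bray_curtis <- d
    dm <- as.matrix(d)
    write_tsv(data.frame(sample_id = rownames(dm), dm, check.names = FALSE),
              out("bray_curtis.tsv"))

    stage <- "ordinate"
    ord <- pcoa(d, n_axes = 2)
    res$pcoa <- ord
    write_tsv(data.frame(sample_id = rownames(ord$points), ord$points,
                         class = cls[rownames(ord$points)],
                         check.names = FALSE),
              out("pcoa.tsv"))

    stage <- "permanova"
    samp_order <- colnames(asv_counts(filtered))
    perm <- pairwise_permanova(
      d, cls[samp_order],
      contrasts = list(c("mother.GDM", "mother.control"),
                       c("T1.GDM", "T1.control"),
                       c("T2.GDM", "T2.control")),
      n_permutations = cfg$permanova$n_permutations,
      seed = stage_seed(cfg$seed, "permanova"))
    res$permanova <- perm
    write_tsv(cbind(as.data.frame(perm), seed = stage_seed(cfg$seed, "permanova")),
              out("permanova_pairwise.tsv"))

    stage <- "diffabund"
    mothers <- metadata[metadata$role == "mother", ]
    mtab <- filtered[, mothers$sample_id]
    da <- nb_wald_test(mtab, factor(mothers$group,
                                    levels = c("control", "GDM")))
    res$differential <- da
    write_tsv(as.data.frame(da), out("differential_mothers.tsv"))
    markers <- select_markers(da, lfc_min = cfg$markers$lfc_min,
                              alpha = cfg$markers$alpha)
    res$markers <- markers
    jsonlite::write_json(
      list(lfc_min = cfg$markers$lfc_min, alpha = cfg$markers$alpha,
           markers = as.data.frame(markers)),
      out("markers.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "columns")

    stage <- "core"
    res$core <- list()
    for (grp in c("GDM", "control")) {
      vag <- mothers$sample_id[mothers$group == grp &
        (!"delivery_mode" %in% names(mothers) |
           mothers$delivery_mode == "vaginal")]
      if (!length(vag)) next
      core <- core_microbiome(filtered, vag,
                              prevalence_min = cfg$core$prevalence,
                              detection = cfg$core$detection)
      res$core[[grp]] <- core
      write_tsv(as.data.frame(core), out(sprintf("core_%s.tsv", grp)))
      if (nrow(core)) {
        infants <- metadata$sample_id[metadata$role == "infant" &
                                        metadata$group == grp]
        trk <- track_set_in_samples(core$asv_id, filtered, infants)
        trk <- trk[ward_cluster_order(trk), , drop = FALSE]
        write_tsv(data.frame(asv_id = rownames(trk), trk, check.names = FALSE),
                  out(sprintf("core_%s_in_infants.tsv", grp)))
      }
    }

    stage <- "transmit"
    trans <- cohort_transmission(
      dyads, filtered, markers = markers,
      complete_pairs_only = cfg$transmission$complete_pairs_only,
      vaginal_only = cfg$transmission$vaginal_only)
    res$transmission <- trans
    write_tsv(trans$records, out("transmission_records.tsv"))
    jsonlite::write_json(trans$summary, out("transmission_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (nrow(markers)) {
      write_tsv(marker_sharing_frequency(dyads, markers, filtered),
                out("marker_sharing.tsv"))
    }

    stage <- "sourcetrack"
    st <- track_cohort_sources(
      dyads, filtered,
      include_unknown = cfg$sourcetrack$include_unknown,
      pseudocount = cfg$sourcetrack$pseudocount,
      max_iter = cfg$sourcetrack$max_iter, tol = cfg$sourcetrack$tol)
    res$sources <- st
    write_tsv(as.data.frame(st), out("source_proportions.tsv"))

    stage <- "summary"
    summary_obj <- list(
      package = "dyadtrack",
      version = as.character(utils::packageVersion("dyadtrack")),
      seed = cfg$seed,
      stage_seeds = list(simulate = stage_seed(cfg$seed, "simulate"),
                         permanova = stage_seed(cfg$seed, "permanova")),
      thresholds = list(filter_min_total = cfg$filter$min_total,
                        marker_lfc_min = cfg$markers$lfc_min,
                        marker_alpha = cfg$markers$alpha,
                        core_prevalence = cfg$core$prevalence,
                        n_permutations = cfg$permanova$n_permutations),
      n_samples = ncol(asv_counts(tab)),
      n_asvs_raw = nrow(asv_counts(tab)),
      n_asvs_filtered = nrow(asv_counts(filtered)),
      n_dyads = nrow(dyads),
      n_markers = nrow(markers),
      files = basename(files))
    jsonlite::write_json(summary_obj, file.path(cfg$outdir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    res$summary <- summary_obj
  }, error = function(e) {
    stopf("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}
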