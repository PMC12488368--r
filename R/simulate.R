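#' Simulation parameters for a synthetic dyad cohort
#'
#' Collects and validates the parameters of the generative model used by
#' [simulate_cohort()]. Defaults emulate a cohort of 23 GDM and 10 control
#' complete, vaginally delivered mother-infant dyads sequenced to 10,000
#' reads per sample, with 10 GDM-enriched marker ASVs planted in mothers at
#' log2 fold change 4.
#'
#' @param n_gdm_dyads,n_control_dyads Number of dyads per group.
#' @param n_asvs Size of the shared gut ASV pool.
#' @param n_markers Number of ASVs enriched in GDM mothers.
#' @param marker_log2fc Planted enrichment of marker ASVs (log2 scale).
#' @param marker_base_abundance Baseline relative abundance near which
#'   marker ASVs are planted (default 1e-3, i.e. moderate-abundance taxa:
#'   detectable at typical sequencing depths, but carrying little total
#'   mass, so renormalization after enrichment barely attenuates the
#'   planted fold change).
#' @param tau Mean mother-to-meconium (T1) transmission fraction in `[0,1]`:
#'   the share of the T1 community inherited from the mother, the remainder
#'   coming from an environmental pool.
#' @param rho Mean T1-to-T2 retention probability in `[0,1]`: each T1 ASV is
#'   independently retained at 6 weeks with this probability.
#' @param depth Sequencing depth (reads per sample).
#' @param overdispersion Dirichlet concentration scaling inter-subject
#'   variation; smaller values give more variable communities.
#' @param base_concentration Symmetric Dirichlet parameter generating the
#'   baseline community; values below 1 give realistic uneven abundance.
#' @param env_pool_size Number of environment-only ASVs (never present in
#'   maternal communities).
#' @param t2_mother_weight Share of the non-retained T2 mass re-seeded from
#'   the maternal community (the rest comes from a fresh environmental
#'   draw); raising it reproduces a dominant maternal source at T2.
#' @param tau_concentration,rho_concentration Beta concentration of the
#'   per-dyad draws around `tau` and `rho`; small values reproduce the wide
#'   per-dyad spread of sharing percentages seen in real dyad cohorts.
#' @param n_gdm_no_t2 Number of GDM dyads whose T2 sample is missing
#'   (absent slot, not an empty community).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @return A validated list of class `simulation_params`.
#' @export
simulation_params <- function(n_gdm_dyads = 23, n_control_dyads = 10,
                              n_asvs = 300, n_markers = 10,
                              marker_log2fc = 4, marker_base_abundance = 1e-3,
                              tau = 0.35, rho = 0.5,
                              depth = 1e4, overdispersion = 50,
                              base_concentration = 0.3, env_pool_size = 100,
                              t2_mother_weight = 0.5,
                              tau_concentration = 6, rho_concentration = 6,
                              n_gdm_no_t2 = 0, seed = 1) {
  p <- list(n_gdm_dyads = n_gdm_dyads, n_control_dyads = n_control_dyads,
            n_asvs = n_asvs, n_markers = n_markers,
            marker_log2fc = marker_log2fc,
            marker_base_abundance = marker_base_abundance,
            tau = tau, rho = rho,
            depth = depth, overdispersion = overdispersion,
            base_concentration = base_concentration,
            env_pool_size = env_pool_size,
            t2_mother_weight = t2_mother_weight,
            tau_concentration = tau_concentration,
            rho_concentration = rho_concentration,
            n_gdm_no_t2 = n_gdm_no_t2, seed = seed)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]])) {
      stopf("parameter '%s' must be a single finite number", nm)
    }
  }
  for (nm in c("tau", "rho", "t2_mother_weight")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stopf("parameter '%s' must lie in [0, 1]", nm)
  }
  if (p$depth < 1) stopf("depth must be >= 1")
  if (p$n_asvs < 1) stopf("n_asvs must be >= 1")
  if (p$env_pool_size < 0) stopf("env_pool_size must be >= 0")
  if (p$n_markers < 0 || p$n_markers > p$n_asvs) {
    stopf("n_markers must lie in [0, n_asvs]")
  }
  if (p$overdispersion <= 0 || p$base_concentration <= 0 ||
      p$tau_concentration <= 0 || p$rho_concentration <= 0) {
    stopf("concentration parameters must be positive")
  }
  if (p$n_gdm_dyads < 1 || p$n_control_dyads < 0) {
    stopf("dyad counts must be positive")
  }
  if (p$n_gdm_no_t2 < 0 || p$n_gdm_no_t2 > p$n_gdm_dyads) {
    stopf("n_gdm_no_t2 must lie in [0, n_gdm_dyads]")
  }
  p$seed <- as.integer(p$seed)
  class(p) <- "simulation_params"
  p
}

#' Simulate a synthetic mother-infant dyad cohort
#'
#' Generates an ASV count table, sample metadata and ground truth for a
#' cohort of GDM and control dyads under a Dirichlet-multinomial model:
#'
#' 1. a baseline relative-abundance vector over the gut ASV pool is drawn
#'    from a symmetric Dirichlet;
#' 2. marker ASVs are enriched `2^marker_log2fc`-fold in the GDM group mean
#'    (renormalized); each mother's composition is a Dirichlet draw around
#'    her group mean with the given concentration;
#' 3. the meconium (T1) composition is `tau_d x mother + (1 - tau_d) x
#'    environment`, with per-dyad `tau_d ~ Beta` centred on `tau` and an
#'    environment drawn from a disjoint environmental ASV pool;
#' 4. the 6-week (T2) composition keeps each T1 ASV independently with
#'    per-dyad probability `rho_d` and re-seeds the lost mass from a
#'    mother/fresh-environment admixture weighted by `t2_mother_weight`;
#' 5. observed counts are multinomial draws of `depth` reads per sample.
#'
#' Markers are planted in mothers only; any marker signal in infants arises
#' through the transmission mechanism, so marker-transfer detection is a
#' genuine test of the downstream analysis.
#'
#' @param params A [simulation_params()] object (or arguments passed to it).
#' @return A list of class `synthetic_cohort` with components `table`
#'   ([asv_table]), `metadata` (sample records, see [read_metadata()]) and
#'   `truth` (per-dyad `tau`/`rho` draws, marker ids with planted log2 fold
#'   change, and per-sample source fractions summing to 1).
#' @examples
#' cohort <- simulate_cohort(simulation_params(n_gdm_dyads = 3,
#'   n_control_dyads = 2, n_asvs = 50, env_pool_size = 10, depth = 1000))
#' cohort$table
#' @export
simulate_cohort <- function(params = simulation_params()) {
  if (!inherits(params, "simulation_params")) {
    stopf("params must be created by simulation_params()")
  }
  p <- params
  set.seed(p$seed)

  n_total_asv <- p$n_asvs + p$env_pool_size
  asv_ids <- sprintf("ASV%04d", seq_len(n_total_asv))
  gut_idx <- seq_len(p$n_asvs)
  env_idx <- if (p$env_pool_size > 0) p$n_asvs + seq_len(p$env_pool_size) else integer(0)

  # (1) baseline community over the gut pool
  baseline <- rdirichlet1(rep(p$base_concentration, p$n_asvs))
  marker_idx <- if (p$n_markers > 0) {
    # plant markers on moderate-abundance taxa (near marker_base_abundance):
    # abundant enough to be observed at typical depths in both groups, yet
    # carrying little enough total mass that renormalization after the
    # fold-change boost barely attenuates the planted effect
    order(abs(baseline - p$marker_base_abundance))[seq_len(p$n_markers)]
  } else integer(0)
  gdm_mean <- baseline
  gdm_mean[marker_idx] <- gdm_mean[marker_idx] * 2^p$marker_log2fc
  gdm_mean <- gdm_mean / sum(gdm_mean)
  env_baseline <- if (p$env_pool_size > 0) {
    rdirichlet1(rep(p$base_concentration, p$env_pool_size))
  } else numeric(0)

  n_dyads <- p$n_gdm_dyads + p$n_control_dyads
  groups <- c(rep("GDM", p$n_gdm_dyads), rep("control", p$n_control_dyads))
  has_t2 <- rep(TRUE, n_dyads)
  if (p$n_gdm_no_t2 > 0) has_t2[seq_len(p$n_gdm_no_t2)] <- FALSE
  dyad_ids <- sprintf("D%03d", seq_len(n_dyads))

  draw_env <- function() {
    comp <- numeric(n_total_asv)
    if (p$env_pool_size > 0) {
      comp[env_idx] <- rdirichlet1(p$overdispersion * env_baseline)
    }
    comp
  }

  tau_d <- stats::rbeta(n_dyads, p$tau * p$tau_concentration,
                        (1 - p$tau) * p$tau_concentration)
  rho_d <- stats::rbeta(n_dyads, p$rho * p$rho_concentration,
                        (1 - p$rho) * p$rho_concentration)
  if (p$tau == 1) tau_d[] <- 1
  if (p$tau == 0) tau_d[] <- 0
  if (p$rho == 1) rho_d[] <- 1
  if (p$rho == 0) rho_d[] <- 0

  counts <- list(); meta <- list(); src <- list()
  for (d in seq_len(n_dyads)) {
    did <- dyad_ids[d]
    gmean <- if (groups[d] == "GDM") gdm_mean else baseline
    mother_comp <- numeric(n_total_asv)
    mother_comp[gut_idx] <- rdirichlet1(p$overdispersion * gmean)

    env1 <- draw_env()
    t1_comp <- tau_d[d] * mother_comp + (1 - tau_d[d]) * env1
    if (p$env_pool_size == 0) t1_comp <- mother_comp  # no environment to mix

    keep <- stats::rbinom(n_total_asv, 1L, rho_d[d]) == 1L
    retained <- ifelse(keep, t1_comp, 0)
    lost <- 1 - sum(retained)
    env2 <- draw_env()
    reseed <- p$t2_mother_weight * mother_comp +
      (1 - p$t2_mother_weight) * (if (p$env_pool_size > 0) env2 else mother_comp)
    t2_comp <- retained + lost * reseed
    t2_comp <- t2_comp / sum(t2_comp)

    sid <- c(mother = paste0(did, "M"), t1 = paste0(did, "T1"),
             t2 = paste0(did, "T2"))
    comps <- list(mother_comp, t1_comp, if (has_t2[d]) t2_comp else NULL)
    use <- c(TRUE, TRUE, has_t2[d])
    for (k in which(use)) {
      counts[[sid[k]]] <- as.integer(stats::rmultinom(1, p$depth, comps[[k]]))
    }
    meta[[did]] <- data.frame(
      sample_id = sid[use],
      dyad_id = did, group = groups[d],
      role = c("mother", "infant", "infant")[use],
      timepoint = c("antenatal", "T1", "T2")[use],
      delivery_mode = "vaginal", feeding = "breast", antibiotics = "no",
      stringsAsFactors = FALSE)
    t1_env <- if (p$env_pool_size == 0) 0 else 1 - tau_d[d]
    src[[did]] <- data.frame(
      sample_id = sid[use],
      mother = c(1, 1 - t1_env,
                 lost * p$t2_mother_weight +
                   (if (p$env_pool_size == 0) lost * (1 - p$t2_mother_weight) else 0))[use],
      meconium = c(0, 0, sum(retained))[use],
      environment = c(0, t1_env,
                      if (p$env_pool_size == 0) 0 else lost * (1 - p$t2_mother_weight))[use],
      stringsAsFactors = FALSE)
  }

  m <- do.call(cbind, counts)
  rownames(m) <- asv_ids
  colnames(m) <- names(counts)
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  sources <- do.call(rbind, src)
  rownames(sources) <- NULL

  truth <- list(
    dyads = data.frame(dyad_id = dyad_ids, group = groups,
                       tau = tau_d, rho = rho_d, has_t2 = has_t2,
                       stringsAsFactors = FALSE),
    markers = data.frame(asv_id = asv_ids[marker_idx],
                         log2fc = rep(p$marker_log2fc, length(marker_idx)),
                         stringsAsFactors = FALSE),
    sources = sources,
    params = p
  )
  structure(list(table = asv_table(m), metadata = metadata, truth = truth),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  p <- x$truth$params
  cat(sprintf(
    "Synthetic dyad cohort: %d GDM + %d control dyads, %d samples, depth %g\n",
    p$n_gdm_dyads, p$n_control_dyads, ncol(asv_counts(x$table)), p$depth))
  cat(sprintf("  %d gut ASVs (+%d environmental), %d planted markers (log2FC %g)\n",
              p$n_asvs, p$env_pool_size, p$n_markers, p$marker_log2fc))
  cat(sprintf("  tau = %g, rho = %g, seed = %d\n", p$tau, p$rho, p$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the count table and metadata as TSV and the ground truth as JSON.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(table = file.path(dir, "asv_table.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             truth = file.path(dir, "truth.json"))
  write_asv_table(cohort$table, paths[["table"]])
  write_metadata(cohort$metadata, paths[["metadata"]])
  tr <- cohort$truth
  tr$params <- unclass(tr$params)
  jsonlite::write_json(tr, paths[["truth"]], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
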