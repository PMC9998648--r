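#' Run the full connectivity twin pipeline
#'
#' Orchestrates every stage end to end: obtain per-subject ROI time series
#' (either supplied, read from a directory of \code{<subject_id>.tsv}
#' files, or simulated), build significance-masked weighted and binarized
#' FC matrices, extract the link/node/network feature table, fit the twin
#' decomposition, and optionally summarise scenario percentages within
#' RSNs. All parameters and the seed are echoed in the returned
#' \code{config} so a run can be reproduced exactly.
#'
#' @param manifest A \code{twin_manifest}, or path to a manifest file.
#'   Ignored when \code{simulate} is given.
#' @param timeseries Named list of T x N matrices keyed by subject id, or a
#'   directory containing \code{<subject_id>.tsv} files. Ignored when
#'   \code{simulate} is given.
#' @param simulate Optional list of arguments forwarded to
#'   [simulate_timeseries_cohort()] (e.g. \code{list(base = diag(8),
#'   n_mz = 18, n_dz = 25)}); when present the cohort is simulated instead
#'   of read.
#' @param parcellation ROI labels (default taken from the first series).
#' @param alpha_link Link-significance level for masking (default 0.05).
#' @param tau Binarization threshold (default 0.5).
#' @param alpha_twin Level for the Fisher comparisons (default 0.05).
#' @param rsn_map Optional RSN map (named list or path to YAML) for the
#'   post-hoc summary.
#' @param require_significant_r,double_entry Passed to [twin_fc()].
#' @param seed Seed for Louvain restarts (and simulation when used).
#' @param out_dir Optional directory; when given, the manifest, results
#'   table and RSN summary are written there in the package's text formats.
#' @return List with \code{fit} (a \code{twin_fc} object), \code{features},
#'   \code{rsn_summary} (or NULL) and \code{config}.
#' @export
run_twin_pipeline <- function(manifest = NULL, timeseries = NULL,
                              simulate = NULL, parcellation = NULL,
                              alpha_link = 0.05, tau = 0.5,
                              alpha_twin = 0.05, rsn_map = NULL,
                              require_significant_r = FALSE,
                              double_entry = FALSE, seed = 1L,
                              out_dir = NULL) {
  if (!is.null(simulate)) {
    simulate$seed <- simulate$seed %||% seed
    sim <- do.call(simulate_timeseries_cohort, simulate)
    manifest <- sim$manifest
    timeseries <- sim$series
  } else {
    if (is.null(manifest)) stop("pipeline stage 'manifest': no manifest given")
    if (is.character(manifest)) manifest <- read_pair_manifest(manifest)
    if (is.null(timeseries))
      stop("pipeline stage 'timeseries': no time series given")
    if (is.character(timeseries)) {
      dir <- timeseries
      ids <- c(manifest$twin1_id, manifest$twin2_id)
      paths <- file.path(dir, paste0(ids, ".tsv"))
      missing <- !file.exists(paths)
      if (any(missing))
        stop("pipeline stage 'timeseries': missing file(s) for subject(s) ",
             paste(ids[missing], collapse = ", "))
      parc <- parcellation %||% aal90_labels()
      timeseries <- lapply(paths, read_roi_timeseries, parcellation = parc)
      names(timeseries) <- ids
    }
  }
  manifest <- validate_manifest(as.data.frame(manifest))
  if (is.null(parcellation)) parcellation <- colnames(timeseries[[1]])
  check_parcellation(parcellation)

  cohort <- lapply(timeseries, function(ts) {
    fc <- compute_fc_matrix(ts)
    w <- significance_mask(fc$r, fc$p, alpha = alpha_link)
    list(weighted = w, binary = binarize(w, tau = tau))
  })
  features <- extract_feature_table(cohort, seed = seed)
  fit <- twin_fc(features, manifest, alpha = alpha_twin,
                 require_significant_r = require_significant_r,
                 double_entry = double_entry)

  rsn_summary <- NULL
  if (!is.null(rsn_map)) {
    if (is.character(rsn_map))
      rsn_map <- read_rsn_map(rsn_map, parcellation)
    rsn_summary <- rsn_effect_percentages(fit$results, rsn_map,
                                          parcellation)
  }

  config <- list(alpha_link = alpha_link, tau = tau,
                 alpha_twin = alpha_twin, seed = seed,
                 require_significant_r = require_significant_r,
                 double_entry = double_entry,
                 n_mz = sum(manifest$zygosity == "MZ"),
                 n_dz = sum(manifest$zygosity == "DZ"),
                 n_roi = length(parcellation),
                 simulated = !is.null(simulate))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_pair_manifest(manifest, file.path(out_dir, "manifest.tsv"))
    write_results_table(fit$results, file.path(out_dir, "results.tsv"))
    if (!is.null(rsn_summary))
      utils::write.table(rsn_summary, file.path(out_dir, "rsn_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(fit = fit, features = features, rsn_summary = rsn_summary,
       config = config)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
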