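#' Configuration for an end-to-end segmentation run
#'
#' Bundles every setting of the pipeline with the study-design defaults:
#' eligibility as the top 5% of annual spending among adults, candidate k
#' from 2 to 20, and 500 bootstrap stability replicates. A single master
#' seed fans out to the stage seeds by fixed offsets so one number
#' reproduces the entire run.
#'
#' @param spec A [cohort_spec()] to simulate from, or `NULL` when reading
#'   prepared tables from `input_dir`.
#' @param input_dir Directory with `demographics.csv` / `claims.csv` (used
#'   when `spec` is NULL).
#' @param crosswalk,preventable_map Condition crosswalk and
#'   preventable-flag tables (defaults: the bundled synthetic ones).
#' @param eligibility_quantile Spending tail defining the cohort (default
#'   0.05); `NULL` skips eligibility filtering (cohort already
#'   threshold-defined).
#' @param min_age Minimum age (default 21); `NULL` skips the age filter.
#' @param k Fixed number of clusters; `NULL` (default) selects k from
#'   `k_grid`.
#' @param k_grid Candidate k grid (default 2:20). A single-value grid
#'   behaves like fixing `k`.
#' @param n_restarts k-means restarts (default 10).
#' @param n_replicates Bootstrap stability replicates (default 500).
#' @param seed Master seed.
#' @param out_dir Output directory for the stage artifacts.
#' @param crosswalk_level Condition grouping level (default "2").
#' @return An object of class `hcn_run_config`.
#' @export
run_config <- function(spec = NULL, input_dir = NULL,
                       crosswalk = synthetic_ccs_crosswalk(),
                       preventable_map = synthetic_preventable_flags(),
                       eligibility_quantile = 0.05, min_age = 21,
                       k = NULL, k_grid = 2:20, n_restarts = 10,
                       n_replicates = 500, seed = 1, out_dir = NULL,
                       crosswalk_level = "2") {
  if (is.null(spec) && is.null(input_dir)) {
    abort("provide either `spec` (simulate) or `input_dir` (ingest).")
  }
  if (!is.null(eligibility_quantile) &&
      (eligibility_quantile <= 0 || eligibility_quantile >= 1)) {
    abort("`eligibility_quantile` must lie in (0, 1) or be NULL.")
  }
  structure(list(spec = spec, input_dir = input_dir, crosswalk = crosswalk,
                 preventable_map = preventable_map,
                 eligibility_quantile = eligibility_quantile,
                 min_age = min_age, k = k, k_grid = as.integer(k_grid),
                 n_restarts = as.integer(n_restarts),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), out_dir = out_dir,
                 crosswalk_level = crosswalk_level),
            class = "hcn_run_config")
}

#' Run the full segmentation pipeline
#'
#' Executes the stages in order — simulate (or ingest), cohort + features,
#' select k, fit, stability, profile — collecting every stage artifact and
#' a run manifest (configuration echo, stage seeds, row counts, warnings).
#' With an `out_dir` set, each artifact is also written as CSV/JSON;
#' re-running with the same configuration is byte-identical for all
#' outputs. Stage seeds are derived from the master seed by fixed offsets.
#'
#' @param config An [run_config()] object.
#' @return An object of class `hcn_run`: list with `patient_years`,
#'   `cohort_patient_years`, `features`, `kcurve` (or NULL), `model`,
#'   `stability`, `profiles`, `deviations`, `labels`, `heatmap`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "hcn_run_config")) abort("`config` must come from run_config().")
  stages <- character(0)
  warnings <- list()
  seeds <- list(master = config$seed,
                simulate = if (!is.null(config$spec)) config$spec$seed else NA,
                kmeans = derive_seed(config$seed, 101),
                stability = derive_seed(config$seed, 202))

  # --- stage 1: simulate or ingest ---------------------------------------
  if (!is.null(config$spec)) {
    cohort <- generate_cohort(config$spec, make_claims = FALSE)
    patient_years <- cohort$patient_years
    stages <- c(stages, "simulate")
  } else {
    tables <- read_claims_tables(config$input_dir)
    patient_years <- build_patient_years(tables$demographics, tables$claims,
                                         config$crosswalk,
                                         config$preventable_map,
                                         level = config$crosswalk_level,
                                         quiet = TRUE)
    unm <- attr(patient_years, "unmapped")
    if (!is.null(unm) && unm[["lines"]] > 0) {
      warnings$unmapped_codes <- as.list(unm)
    }
    stages <- c(stages, "ingest")
  }
  if (nrow(patient_years) == 0) abort("stage cohort: no patients to analyse.")

  # --- stage 2: cohort selection and feature assembly --------------------
  cohort_py <- patient_years
  if (!is.null(config$eligibility_quantile)) {
    cohort_py <- select_eligible(patient_years,
                                 quantile = config$eligibility_quantile,
                                 min_age = config$min_age)
  } else if (!is.null(config$min_age)) {
    cohort_py <- dplyr::filter(cohort_py, .data$age >= config$min_age)
  }
  if (nrow(cohort_py) == 0) abort("stage cohort: eligibility selection left no patients.")
  features <- polar_encode(cohort_py)
  stages <- c(stages, "features")

  # --- stage 3: number of clusters ---------------------------------------
  kcurve <- NULL
  if (is.null(config$k) && length(config$k_grid) > 1) {
    kcurve <- select_k(features, k_grid = config$k_grid,
                       seed = seeds$kmeans, n_restarts = config$n_restarts)
    k_use <- kcurve$selected_k
    stages <- c(stages, "select-k")
  } else {
    k_use <- config$k %||% config$k_grid[1]
    warnings$select_k_skipped <- sprintf(
      "k fixed at %d; selection stage skipped.", k_use)
  }

  # --- stage 4: reference fit --------------------------------------------
  model <- fit_kmeans(features, k_use, seed = seeds$kmeans,
                      n_restarts = config$n_restarts)
  stages <- c(stages, "fit")

  # --- stage 5: stability -------------------------------------------------
  stability <- run_stability(features, model,
                             n_replicates = config$n_replicates,
                             seed = seeds$stability,
                             n_restarts = config$n_restarts)
  if (stability$n_skipped > 0) {
    warnings$skipped_replicates <- stability$n_skipped
  }
  stages <- c(stages, "stability")

  # --- stage 6: profiles ---------------------------------------------------
  profiles <- profile_clusters(cohort_py, model$assignments)
  deviations <- withCallingHandlers(
    rank_deviations(profiles),
    message = function(m) {
      warnings$zero_variance_features <<- conditionMessage(m)
      invokeRestart("muffleMessage")
    }
  )
  labels <- suggest_label(deviations)
  heatmap <- export_heatmap_table(profiles)
  stages <- c(stages, "profile")

  manifest <- list(
    stages = stages,
    seeds = seeds,
    selected_k = k_use,
    n_input_patients = nrow(patient_years),
    n_cohort_patients = nrow(cohort_py),
    n_features = ncol(features$values),
    n_replicates = config$n_replicates,
    n_skipped_replicates = stability$n_skipped,
    eligibility_quantile = config$eligibility_quantile,
    k_grid = config$k_grid,
    n_restarts = config$n_restarts,
    warnings = warnings
  )

  run <- structure(
    list(patient_years = patient_years, cohort_patient_years = cohort_py,
         features = features, kcurve = kcurve, model = model,
         stability = stability, profiles = profiles,
         deviations = deviations, labels = labels, heatmap = heatmap,
         manifest = manifest),
    class = "hcn_run"
  )
  if (!is.null(config$out_dir)) write_run_artifacts(run, config$out_dir)
  run
}

#' @export
print.hcn_run <- function(x, ...) {
  cat("<hcn_run>", x$manifest$n_cohort_patients, "patients,",
      "k =", x$model$k, "\n")
  cat("stages:", paste(x$manifest$stages, collapse = " -> "), "\n")
  invisible(x)
}

write_run_artifacts <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) readr::write_csv(df, file.path(out_dir, name))
  w(run$cohort_patient_years, "patient_year.csv")

  feat <- tibble::as_tibble(run$features$values)
  feat <- dplyr::bind_cols(tibble::tibble(patient_id = run$features$row_ids), feat)
  w(feat, "features.csv")
  jsonlite::write_json(run$features$column_meta,
                       file.path(out_dir, "features_meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  if (!is.null(run$kcurve)) w(run$kcurve$curve, "kcurve.csv")
  jsonlite::write_json(
    list(k = run$model$k, seed = run$model$seed,
         within_sse = run$model$within_sse, n_iter = run$model$n_iter,
         centroids = run$model$centroids),
    file.path(out_dir, "model.json"),
    auto_unbox = TRUE, digits = NA, matrix = "rowmajor", pretty = TRUE)
  w(tibble::tibble(patient_id = run$model$row_ids,
                   cluster = run$model$assignments), "assignments.csv")
  w(run$stability$per_cluster, "stability.csv")
  w(run$stability$replicates, "replicates.csv")
  w(run$profiles$clusters, "profiles.csv")
  w(run$heatmap, "heatmap.csv")
  jsonlite::write_json(run$labels, file.path(out_dir, "labels.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
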