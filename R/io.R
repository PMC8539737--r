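#' Write a synthetic cohort to delimited claims tables
#'
#' Emits the file set consumed by the ingest side of the pipeline:
#' `demographics.csv` (patient_id, age, female, eligibility,
#' race_ethnicity, hospital_days), `claims.csv` (patient_id, service_date
#' ISO-8601, setting in IP/ED/OP, icd9, paid_amount), `truth.csv`
#' (patient_id, true_label) and a machine-readable spec echo
#' `cohort_spec.json`. Hospital days ride on the demographics table because
#' a one-line-per-encounter claims extract cannot carry length of stay.
#' Emitting and re-ingesting reproduces every patient-year aggregate
#' exactly (see [build_patient_years()]).
#'
#' @param cohort A `synthetic_cohort` with a claims table.
#' @param directory Output directory (created if missing).
#' @return Invisibly, a named character vector of the written paths.
#' @export
emit_claims_tables <- function(cohort, directory) {
  if (!inherits(cohort, "synthetic_cohort")) abort("`cohort` must be a synthetic_cohort.")
  if (is.null(cohort$claims)) abort("cohort has no claims table; regenerate with make_claims = TRUE.")
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  py <- cohort$patient_years
  demo <- py[, c("patient_id", "age", "female", "eligibility",
                 "race_ethnicity", "hospital_days")]
  paths <- c(
    demographics = file.path(directory, "demographics.csv"),
    claims = file.path(directory, "claims.csv"),
    truth = file.path(directory, "truth.csv"),
    spec = file.path(directory, "cohort_spec.json")
  )
  readr::write_csv(demo, paths[["demographics"]])
  readr::write_csv(cohort$claims, paths[["claims"]])
  readr::write_csv(tibble::tibble(patient_id = py$patient_id,
                                  true_label = cohort$true_labels),
                   paths[["truth"]])
  spec <- cohort$spec
  echo <- list(
    n_patients = spec$n_patients,
    mixing_weights = spec$mixing_weights,
    condition_prevalence = spec$condition_prevalence,
    demographics = spec$demographics,
    eligibility_prob = spec$eligibility_prob,
    race_prob = spec$race_prob,
    utilization = spec$utilization,
    cost = spec$cost,
    count_model = spec$count_model,
    separation = spec$separation,
    seed = spec$seed
  )
  jsonlite::write_json(echo, paths[["spec"]], auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", pretty = TRUE)
  invisible(paths)
}

#' Read claims tables from a directory
#'
#' Reads `demographics.csv` and `claims.csv` (and `truth.csv` when present)
#' as written by [emit_claims_tables()] or prepared externally in the same
#' shape.
#'
#' @param directory Directory holding the tables.
#' @return A list with tibbles `demographics`, `claims`, and optionally
#'   `truth`.
#' @export
read_claims_tables <- function(directory) {
  demo_path <- file.path(directory, "demographics.csv")
  claims_path <- file.path(directory, "claims.csv")
  if (!file.exists(demo_path) || !file.exists(claims_path)) {
    abort(sprintf("expected demographics.csv and claims.csv under '%s'.", directory))
  }
  demographics <- readr::read_csv(
    demo_path, show_col_types = FALSE,
    col_types = readr::cols(patient_id = readr::col_character(),
                            eligibility = readr::col_character(),
                            race_ethnicity = readr::col_character(),
                            .default = readr::col_double()))
  claims <- readr::read_csv(
    claims_path, show_col_types = FALSE,
    col_types = readr::cols(patient_id = readr::col_character(),
                            service_date = readr::col_date(),
                            setting = readr::col_character(),
                            icd9 = readr::col_character(),
                            paid_amount = readr::col_double()))
  bad <- setdiff(unique(claims$setting), setting_levels())
  if (length(bad) > 0) {
    abort(paste0("claims settings outside the IP/ED/OP vocabulary: ",
                 paste(bad, collapse = ", ")))
  }
  if (any(claims$paid_amount < 0)) abort("claims paid_amount must be non-negative.")
  out <- list(demographics = demographics, claims = claims)
  truth_path <- file.path(directory, "truth.csv")
  if (file.exists(truth_path)) {
    out$truth <- readr::read_csv(
      truth_path, show_col_types = FALSE,
      col_types = readr::cols(patient_id = readr::col_character(),
                              true_label = readr::col_integer()))
  }
  out
}
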