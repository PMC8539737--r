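#' Select the eligible high-cost cohort by spending quantile
#'
#' Applies the threshold rule that defines high-cost high-need status:
#' adults (age at or above `min_age`) in the top `quantile` of annual
#' spending. The age filter is applied first, then the spending rule among
#' the remaining patients: the top `ceiling(n * quantile)` spenders are
#' taken, and any further patient tied with the boundary spend is included
#' as well (a deterministic, conservative tie rule).
#'
#' @param patient_years Patient-year tibble with an `annual_spend` column
#'   (and `age` unless `min_age = NULL`).
#' @param quantile Eligibility tail probability in (0, 1); default 0.05,
#'   i.e. the top 5% of spending.
#' @param min_age Minimum age in years (default 21); `NULL` skips the
#'   age filter.
#' @return The eligible subset of `patient_years`, in the original order.
#' @export
select_eligible <- function(patient_years, quantile = 0.05, min_age = 21) {
  if (nrow(patient_years) == 0) abort("`patient_years` is empty.")
  if (!is.numeric(quantile) || length(quantile) != 1 ||
      quantile <= 0 || quantile >= 1) {
    abort("`quantile` must be a single probability strictly inside (0, 1).")
  }
  py <- patient_years
  if (!is.null(min_age)) {
    if (!"age" %in% names(py)) abort("`patient_years` needs an `age` column.")
    py <- dplyr::filter(py, .data$age >= min_age)
    if (nrow(py) == 0) abort("no patients remain after the age filter.")
  }
  spend <- py$annual_spend
  if (length(unique(spend)) == 1) {
    abort(paste0("all annual spends are equal; the spending quantile is ",
                 "degenerate. Deduplicate or set an explicit tie policy ",
                 "before selecting the cohort."))
  }
  k_top <- ceiling(nrow(py) * quantile)
  threshold <- sort(spend, decreasing = TRUE)[k_top]
  dplyr::filter(py, .data$annual_spend >= threshold)
}

#' Group claims into per-patient condition indicators
#'
#' A patient's flag for a condition category is 1 iff at least one claim
#' carries a diagnosis code mapping to that category at the requested
#' crosswalk level. Prefix wildcarding applies, longest matching prefix
#' wins. Codes with no match at the level are tallied (attribute
#' `unmapped`, plus a message) but never fatal.
#'
#' @param claims Claims tibble (`patient_id`, `icd9`, ...).
#' @param crosswalk Crosswalk tibble (see [read_crosswalk()]).
#' @param level Crosswalk level to group at (default `"2"`).
#' @param patient_ids Optional full patient universe; patients without
#'   claims get all-zero flags.
#' @param quiet Suppress the unmapped-code message.
#' @return Tibble `patient_id` + one `cond_<category>` 0/1 column per
#'   category at the level, with attribute `unmapped` (named integer:
#'   distinct unmapped codes and total unmapped claim lines).
#' @export
group_conditions <- function(claims, crosswalk, level = "2",
                             patient_ids = NULL, quiet = FALSE) {
  crosswalk <- validate_crosswalk(crosswalk)
  cats <- crosswalk_categories(crosswalk, level)
  ids <- patient_ids %||% unique(claims$patient_id)

  flags <- matrix(0L, nrow = length(ids), ncol = length(cats),
                  dimnames = list(NULL, paste0("cond_", cats)))
  unmapped <- c(codes = 0L, lines = 0L)
  if (nrow(claims) > 0) {
    cat_of <- match_categories(claims$icd9, crosswalk, level)
    miss <- is.na(cat_of)
    unmapped <- c(codes = length(unique(claims$icd9[miss])),
                  lines = sum(miss))
    if (unmapped[["lines"]] > 0 && !quiet) {
      message(sprintf("group_conditions: %d claim line(s) with %d distinct code(s) unmapped at level %s.",
                      unmapped[["lines"]], unmapped[["codes"]], level))
    }
    hit <- !miss & claims$patient_id %in% ids
    if (any(hit)) {
      ri <- match(claims$patient_id[hit], ids)
      ci <- match(cat_of[hit], cats)
      flags[cbind(ri, ci)] <- 1L
    }
  }
  out <- dplyr::bind_cols(tibble::tibble(patient_id = ids),
                          tibble::as_tibble(flags))
  attr(out, "unmapped") <- unmapped
  out
}

#' Count preventable utilization from flagged diagnosis codes
#'
#' Counts inpatient (resp. emergency) claim lines whose diagnosis code is
#' flagged in the preventable-utilization table for that setting. This is a
#' pluggable code-to-flag rule, not a reimplementation of any licensed
#' preventable-utilization algorithm. By construction the counts never
#' exceed the patient's total IP / ED encounter counts.
#'
#' @param claims Claims tibble.
#' @param preventable_map Flag table (see [read_preventable_flags()]).
#' @param patient_ids Optional full patient universe.
#' @return Tibble `patient_id`, `preventable_admissions`,
#'   `preventable_ed_visits`.
#' @export
flag_preventable <- function(claims, preventable_map, patient_ids = NULL) {
  ids <- patient_ids %||% unique(claims$patient_id)
  out <- tibble::tibble(patient_id = ids,
                        preventable_admissions = 0L,
                        preventable_ed_visits = 0L)
  if (nrow(claims) == 0) return(out)
  count_setting <- function(setting) {
    sub <- claims[claims$setting == setting, , drop = FALSE]
    if (nrow(sub) == 0) return(integer(length(ids)))
    flagged <- match_flagged(sub$icd9, preventable_map, setting)
    tab <- table(factor(sub$patient_id[flagged], levels = ids))
    as.integer(tab)
  }
  out$preventable_admissions <- count_setting("IP")
  out$preventable_ed_visits <- count_setting("ED")
  out
}

#' Assemble patient-year records from claims tables
#'
#' Builds one analytic row per patient: demographics from the demographics
#' table; admissions and ED visits counted as IP / ED claim lines;
#' condition indicators via [group_conditions()]; preventable counts via
#' [flag_preventable()]; annual spend as the sum of paid amounts. This is
#' the ingest twin of [emit_claims_tables()]: emit then ingest reproduces
#' the generator's patient-year aggregates exactly.
#'
#' @param demographics Demographics tibble (`patient_id`, `age`, `female`,
#'   `eligibility`, `race_ethnicity`, `hospital_days`).
#' @param claims Claims tibble.
#' @param crosswalk Condition crosswalk.
#' @param preventable_map Preventable-flag table.
#' @param level Crosswalk grouping level (default `"2"`).
#' @param quiet Suppress the unmapped-code message.
#' @return Patient-year tibble in the same shape as
#'   `generate_cohort()$patient_years`.
#' @export
build_patient_years <- function(demographics, claims, crosswalk,
                                preventable_map, level = "2", quiet = FALSE) {
  ids <- demographics$patient_id
  stray <- setdiff(unique(claims$patient_id), ids)
  if (length(stray) > 0) {
    warn(sprintf("%d claim patient id(s) missing from demographics; their claims are dropped.",
                 length(stray)))
    claims <- claims[claims$patient_id %in% ids, , drop = FALSE]
  }
  flags <- group_conditions(claims, crosswalk, level = level,
                            patient_ids = ids, quiet = quiet)
  prev <- flag_preventable(claims, preventable_map, patient_ids = ids)
  count_lines <- function(setting) {
    as.integer(table(factor(claims$patient_id[claims$setting == setting],
                            levels = ids)))
  }
  spend <- claims |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(annual_spend = sum(.data$paid_amount), .groups = "drop")

  out <- tibble::tibble(
    patient_id = ids,
    age = as.integer(demographics$age),
    female = as.integer(demographics$female),
    eligibility = demographics$eligibility,
    race_ethnicity = demographics$race_ethnicity
  )
  out <- dplyr::bind_cols(out, flags[, -1, drop = FALSE])
  out$admissions <- count_lines("IP")
  out$hospital_days <- as.integer(demographics$hospital_days)
  out$ed_visits <- count_lines("ED")
  out$preventable_admissions <- prev$preventable_admissions
  out$preventable_ed_visits <- prev$preventable_ed_visits
  out$annual_spend <- round(spend$annual_spend[match(ids, spend$patient_id)], 2)
  out$annual_spend[is.na(out$annual_spend)] <- 0
  attr(out, "unmapped") <- attr(flags, "unmapped")
  out
}
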