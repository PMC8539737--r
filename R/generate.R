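#' Generate a synthetic patient-year cohort with planted cluster structure
#'
#' Draws a cohort from a [cohort_spec()]: planted cluster labels from the
#' mixing weights, condition indicators independently per category given
#' the cluster (after applying the separation control), demographics from
#' the per-cluster distributions, utilization counts from cluster-conditional
#' count distributions (negative binomial when overdispersed), preventable
#' counts as binomial thinnings of their parent counts (so the per-record
#' inequality `preventable <= parent` holds exactly), and annual spend as
#' log-normal noise around a linear index of utilization.
#'
#' When `make_claims = TRUE` (only supported for specs whose condition
#' categories are covered by [synthetic_code_pool()], such as
#' [fixture_cohort_spec()]), a long-format claims table is also constructed
#' that is exactly consistent with the patient-year aggregates: one
#' outpatient line per active condition category, one line per inpatient /
#' ED encounter carrying a diagnosis from the patient's active categories
#' (flagged codes for exactly the preventable encounters), and paid amounts
#' that sum to the patient's annual spend to the cent.
#'
#' @param spec A [cohort_spec()].
#' @param make_claims Also build the claims table (default TRUE).
#' @return An object of class `synthetic_cohort`: a list with
#'   `patient_years` (tibble, one row per patient), `true_labels` (integer
#'   vector of planted clusters), `claims` (tibble or NULL), and `spec`.
#' @examples
#' coh <- generate_cohort(fixture_cohort_spec(n_patients = 200))
#' dplyr::count(coh$patient_years, female)
#' @export
generate_cohort <- function(spec, make_claims = TRUE) {
  spec <- validate_cohort_spec(spec)
  n <- spec$n_patients
  K <- length(spec$mixing_weights)
  cats <- colnames(spec$condition_prevalence)

  if (n == 0) {
    py <- empty_patient_years(cats)
    out <- structure(list(patient_years = py, true_labels = integer(0),
                          claims = if (make_claims) empty_claims() else NULL,
                          spec = spec),
                     class = "synthetic_cohort")
    return(out)
  }

  with_seed(spec$seed, {
    labels <- sample.int(K, n, replace = TRUE, prob = spec$mixing_weights)

    Peff <- effective_prevalence(spec)
    flags <- matrix(runif(n * length(cats)) < Peff[labels, , drop = FALSE],
                    nrow = n)
    storage.mode(flags) <- "integer"
    colnames(flags) <- cats

    d <- spec$demographics
    age <- pmax(0L, as.integer(round(rnorm(n, d$age_mean[labels], d$age_sd[labels]))))
    female <- rbinom(n, 1L, d$p_female[labels])
    eligibility <- sample_categorical_by_cluster(labels, spec$eligibility_prob)
    race <- sample_categorical_by_cluster(labels, spec$race_prob)

    u <- spec$utilization
    admissions <- draw_counts(u$adm_mean[labels], u$adm_sd[labels], spec$count_model)
    ed_visits <- draw_counts(u$ed_mean[labels], u$ed_sd[labels], spec$count_model)
    los <- ifelse(u$adm_mean > 0, u$days_mean / u$adm_mean, 0)
    extra_days <- rpois(n, admissions * pmax(los[labels] - 1, 0))
    hospital_days <- ifelse(admissions > 0, admissions + extra_days, 0L)
    preventable_admissions <- rbinom(n, admissions, u$p_prev_adm[labels])
    preventable_ed_visits <- rbinom(n, ed_visits, u$p_prev_ed[labels])

    cost <- spec$cost
    index <- cost$base + cost$coef_adm * admissions +
      cost$coef_day * hospital_days + cost$coef_ed * ed_visits
    annual_spend <- round(exp(log(index) + rnorm(n, 0, cost$sdlog)), 2)
    n_claims <- admissions + ed_visits + rowSums(flags)
    annual_spend[n_claims == 0] <- 0

    patient_id <- sprintf("P%06d", seq_len(n))
    py <- tibble::tibble(
      patient_id = patient_id, age = age, female = as.integer(female),
      eligibility = eligibility, race_ethnicity = race
    )
    py <- dplyr::bind_cols(
      py,
      tibble::as_tibble(flags, .name_repair = ~ paste0("cond_", cats))
    )
    py$admissions <- as.integer(admissions)
    py$hospital_days <- as.integer(hospital_days)
    py$ed_visits <- as.integer(ed_visits)
    py$preventable_admissions <- as.integer(preventable_admissions)
    py$preventable_ed_visits <- as.integer(preventable_ed_visits)
    py$annual_spend <- annual_spend

    claims <- if (make_claims) build_claims(py, flags, cats) else NULL
  })

  structure(list(patient_years = py, true_labels = as.integer(labels),
                 claims = claims, spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$patient_years), "patients,",
      length(x$spec$mixing_weights), "planted clusters,",
      if (is.null(x$claims)) "no claims table" else
        paste0(nrow(x$claims), " claim lines"), "\n")
  invisible(x)
}

empty_patient_years <- function(cats) {
  py <- tibble::tibble(patient_id = character(0), age = integer(0),
                       female = integer(0), eligibility = character(0),
                       race_ethnicity = character(0))
  for (cat in cats) py[[paste0("cond_", cat)]] <- integer(0)
  py$admissions <- integer(0); py$hospital_days <- integer(0)
  py$ed_visits <- integer(0); py$preventable_admissions <- integer(0)
  py$preventable_ed_visits <- integer(0); py$annual_spend <- numeric(0)
  py
}

empty_claims <- function() {
  tibble::tibble(patient_id = character(0),
                 service_date = as.Date(character(0)),
                 setting = character(0), icd9 = character(0),
                 paid_amount = numeric(0))
}

sample_categorical_by_cluster <- function(labels, prob_matrix) {
  out <- character(length(labels))
  lev <- colnames(prob_matrix)
  for (k in sort(unique(labels))) {
    idx <- which(labels == k)
    out[idx] <- sample(lev, length(idx), replace = TRUE, prob = prob_matrix[k, ])
  }
  out
}

# Negative binomial when the stated SD implies overdispersion, Poisson
# otherwise (or as forced by `model`).
draw_counts <- function(mu, sd, model) {
  n <- length(mu)
  out <- integer(n)
  v <- sd^2
  use_nb <- switch(model,
                   auto = v > mu & mu > 0,
                   nbinom = mu > 0 & v > mu,
                   poisson = rep(FALSE, n))
  if (any(use_nb)) {
    size <- mu[use_nb]^2 / (v[use_nb] - mu[use_nb])
    out[use_nb] <- rnbinom(sum(use_nb), size = size, mu = mu[use_nb])
  }
  if (any(!use_nb)) out[!use_nb] <- rpois(sum(!use_nb), mu[!use_nb])
  out
}

# Build a claims table exactly consistent with the patient-year aggregates.
build_claims <- function(py, flags, cats) {
  pool <- synthetic_code_pool()
  missing_cats <- setdiff(cats, names(pool))
  if (length(missing_cats) > 0) {
    abort(paste0("claims synthesis needs diagnosis codes for every condition ",
                 "category; no codes for: ", paste(missing_cats, collapse = ", "),
                 ". Use make_claims = FALSE or the fixture categories."))
  }
  n <- nrow(py)
  act <- apply(flags == 1L, 1, which, simplify = FALSE)

  # outpatient lines: one per active condition category
  op_idx <- which(flags == 1L, arr.ind = TRUE)
  op_idx <- op_idx[order(op_idx[, 1], op_idx[, 2]), , drop = FALSE]
  op_codes <- vapply(op_idx[, 2], function(j) {
    plain <- pool[[cats[j]]]$plain
    plain[sample.int(length(plain), 1)]
  }, character(1))
  op <- tibble::tibble(row = op_idx[, 1], setting = "OP", icd9 = op_codes)

  encounter_lines <- function(counts, prev_counts, slot_prev) {
    rows <- rep(seq_len(n), counts)
    if (length(rows) == 0) {
      return(tibble::tibble(row = integer(0), setting = character(0),
                            icd9 = character(0)))
    }
    flagged <- sequence(counts) <= rep(prev_counts, counts)
    codes <- character(length(rows))
    for (i in unique(rows)) {
      sel <- which(rows == i)
      acats <- act[[i]]
      for (s in sel) {
        cat_id <- if (length(acats) > 0) {
          cats[acats[sample.int(length(acats), 1)]]
        } else ".filler"
        codes[s] <- if (flagged[s]) {
          pool[[cat_id]][[slot_prev]]
        } else {
          plain <- pool[[cat_id]]$plain
          plain[sample.int(length(plain), 1)]
        }
      }
    }
    tibble::tibble(row = rows, setting = NA_character_, icd9 = codes)
  }

  ip <- encounter_lines(py$admissions, py$preventable_admissions, "ip_prev")
  ip$setting <- rep("IP", nrow(ip))
  ed <- encounter_lines(py$ed_visits, py$preventable_ed_visits, "ed_prev")
  ed$setting <- rep("ED", nrow(ed))

  cl <- dplyr::bind_rows(ip, ed, op)
  if (nrow(cl) == 0) return(empty_claims())
  cl <- cl[order(cl$row), , drop = FALSE]
  cl$service_date <- as.Date("2013-01-01") + sample.int(365, nrow(cl), replace = TRUE) - 1L

  # allocate each patient's annual spend over its claim lines, exact in cents
  cl$paid_amount <- 0
  for (i in unique(cl$row)) {
    sel <- which(cl$row == i)
    total <- py$annual_spend[i]
    w <- runif(length(sel))
    cum <- round(total * cumsum(w) / sum(w), 2)
    cl$paid_amount[sel] <- diff(c(0, cum))
  }

  tibble::tibble(patient_id = py$patient_id[cl$row],
                 service_date = cl$service_date,
                 setting = cl$setting, icd9 = cl$icd9,
                 paid_amount = cl$paid_amount)
}
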