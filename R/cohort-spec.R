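#' Medicaid eligibility program and race/ethnicity levels used throughout
#'
#' Closed vocabularies for the categorical demographic variables: the four
#' Medicaid eligibility pathways (TANF, SSI, Expansion, Medicare-eligible)
#' and race/ethnicity including an explicit "Missing" level, which is common
#' in claims extracts and is treated as an ordinary category rather than
#' being imputed.
#'
#' @name vocabularies
#' @keywords internal
NULL

eligibility_levels <- function() c("TANF", "SSI", "Expansion", "Medicare-eligible")
race_levels <- function() c("White", "Black", "Hispanic", "Asian", "Other", "Missing")
setting_levels <- function() c("IP", "ED", "OP")

#' Specify a synthetic patient-year cohort with planted cluster structure
#'
#' A `cohort_spec` fully determines a synthetic HCHN-style cohort: how many
#' patients, how they split across planted clusters, the per-cluster
#' Bernoulli prevalence of each condition category, per-cluster demographic
#' distributions, per-cluster utilization count distributions (with
#' preventable utilization as a binomial thinning of its parent count), and
#' a heavy-tailed annual spend model linked to utilization.
#'
#' @param n_patients Number of patients to generate (non-negative integer).
#' @param mixing_weights Numeric vector, one probability per planted
#'   cluster; must sum to 1 (tolerance 1e-12).
#' @param condition_prevalence Numeric matrix, planted cluster x condition
#'   category, of Bernoulli probabilities in \[0, 1\]. Column names are the
#'   condition category ids.
#' @param demographics Data frame with one row per planted cluster and
#'   columns `age_mean`, `age_sd` (years) and `p_female`.
#' @param eligibility_prob Matrix (cluster x 4) of probabilities over the
#'   eligibility programs `TANF`, `SSI`, `Expansion`, `Medicare-eligible`;
#'   each row sums to 1.
#' @param race_prob Matrix (cluster x 6) of probabilities over
#'   race/ethnicity levels `White`, `Black`, `Hispanic`, `Asian`, `Other`,
#'   `Missing`; each row sums to 1.
#' @param utilization Data frame with one row per planted cluster and
#'   columns `adm_mean`, `adm_sd`, `days_mean`, `ed_mean`, `ed_sd`,
#'   `p_prev_adm`, `p_prev_ed`. Counts are drawn from a negative binomial
#'   when the stated SD implies overdispersion (variance > mean), otherwise
#'   from a Poisson; preventable counts are binomial thinnings with the
#'   stated probabilities, so preventable counts can never exceed their
#'   parent counts.
#' @param cost Named list with elements `base`, `coef_adm`, `coef_day`,
#'   `coef_ed` (currency weights of the linear utilization index) and
#'   `sdlog` (log-normal noise SD). Spend is
#'   `exp(log(base + coefs . utilization) + N(0, sdlog^2))`, a heavy-tailed
#'   distribution whose upper tail drives quantile-based eligibility.
#' @param count_model `"auto"` (negative binomial when overdispersed,
#'   Poisson otherwise), `"nbinom"`, or `"poisson"` (ignores the SDs).
#' @param separation Non-negative scalar controlling how far cluster
#'   prevalences sit from the population mean. Separation acts
#'   multiplicatively on the logit scale:
#'   `logit(p') = logit(p_pop) + separation * (logit(p_k) - logit(p_pop))`,
#'   so probabilities stay inside (0, 1) at any separation. `1` reproduces
#'   the stated prevalences, `0` collapses all clusters onto the population
#'   mean, values above 1 sharpen the planted structure.
#' @param seed Integer seed; the same spec (including seed) always yields a
#'   byte-identical cohort.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [fixture_cohort_spec()]
#' @export
cohort_spec <- function(n_patients,
                        mixing_weights,
                        condition_prevalence,
                        demographics,
                        eligibility_prob,
                        race_prob,
                        utilization,
                        cost = list(base = 2000, coef_adm = 3000, coef_day = 1200,
                                    coef_ed = 350, sdlog = 0.7),
                        count_model = c("auto", "nbinom", "poisson"),
                        separation = 1,
                        seed = 1) {
  count_model <- match.arg(count_model)
  spec <- structure(
    list(
      n_patients = as.integer(n_patients),
      mixing_weights = as.numeric(mixing_weights),
      condition_prevalence = as.matrix(condition_prevalence),
      demographics = tibble::as_tibble(demographics),
      eligibility_prob = as.matrix(eligibility_prob),
      race_prob = as.matrix(race_prob),
      utilization = tibble::as_tibble(utilization),
      cost = cost,
      count_model = count_model,
      separation = as.numeric(separation),
      seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat("  patients:        ", x$n_patients, "\n", sep = "")
  cat("  planted clusters:", length(x$mixing_weights), "\n")
  cat("  conditions:      ", ncol(x$condition_prevalence), "\n")
  cat("  separation:      ", x$separation, "\n")
  cat("  seed:            ", x$seed, "\n")
  invisible(x)
}

validate_cohort_spec <- function(spec) {
  k <- length(spec$mixing_weights)
  if (is.na(spec$n_patients) || spec$n_patients < 0) {
    abort("`n_patients` must be a non-negative integer.")
  }
  if (k < 1) abort("`mixing_weights` must have at least one cluster.")
  if (abs(sum(spec$mixing_weights) - 1) > 1e-12) {
    abort("`mixing_weights` must sum to 1 (tolerance 1e-12).")
  }
  if (any(spec$mixing_weights < 0)) abort("`mixing_weights` must be non-negative.")

  P <- spec$condition_prevalence
  if (nrow(P) != k) abort("`condition_prevalence` must have one row per cluster.")
  if (is.null(colnames(P))) abort("`condition_prevalence` must have condition category column names.")
  if (any(P < 0 | P > 1)) abort("`condition_prevalence` entries must lie in [0, 1].")

  d <- spec$demographics
  need <- c("age_mean", "age_sd", "p_female")
  if (nrow(d) != k || !all(need %in% names(d))) {
    abort("`demographics` needs one row per cluster and columns age_mean, age_sd, p_female.")
  }
  if (any(d$p_female < 0 | d$p_female > 1)) abort("`demographics$p_female` must lie in [0, 1].")
  if (any(d$age_sd < 0)) abort("`demographics$age_sd` must be non-negative.")

  for (nm in c("eligibility_prob", "race_prob")) {
    M <- spec[[nm]]
    lev <- if (nm == "eligibility_prob") eligibility_levels() else race_levels()
    if (nrow(M) != k || ncol(M) != length(lev)) {
      abort(sprintf("`%s` must be %d x %d (clusters x levels %s).",
                    nm, k, length(lev), paste(lev, collapse = ", ")))
    }
    if (is.null(colnames(M))) colnames(M) <- lev
    if (!identical(colnames(M), lev)) {
      abort(sprintf("`%s` columns must be named %s in order.", nm, paste(lev, collapse = ", ")))
    }
    if (any(M < 0 | M > 1)) abort(sprintf("`%s` entries must lie in [0, 1].", nm))
    if (any(abs(rowSums(M) - 1) > 1e-8)) {
      abort(sprintf("each row of `%s` must sum to 1.", nm))
    }
    spec[[nm]] <- M
  }

  u <- spec$utilization
  need <- c("adm_mean", "adm_sd", "days_mean", "ed_mean", "ed_sd", "p_prev_adm", "p_prev_ed")
  if (nrow(u) != k || !all(need %in% names(u))) {
    abort(paste0("`utilization` needs one row per cluster and columns ",
                 paste(need, collapse = ", "), "."))
  }
  if (any(u$adm_mean < 0 | u$ed_mean < 0 | u$days_mean < 0)) {
    abort("`utilization` means must be non-negative.")
  }
  if (any(u$p_prev_adm < 0 | u$p_prev_adm > 1) || any(u$p_prev_ed < 0 | u$p_prev_ed > 1)) {
    abort("`utilization` thinning probabilities p_prev_adm / p_prev_ed must lie in [0, 1]; this guarantees preventable means never exceed their parent means.")
  }
  if (any(u$days_mean > 0 & u$adm_mean == 0)) {
    abort("`utilization$days_mean` must be 0 where adm_mean is 0 (hospital days require admissions).")
  }

  cost <- spec$cost
  need <- c("base", "coef_adm", "coef_day", "coef_ed", "sdlog")
  if (!all(need %in% names(cost))) {
    abort(paste0("`cost` must contain ", paste(need, collapse = ", "), "."))
  }
  if (cost$base <= 0 || cost$sdlog < 0) abort("`cost$base` must be > 0 and `cost$sdlog` >= 0.")

  if (is.na(spec$separation) || spec$separation < 0) abort("`separation` must be non-negative.")
  spec
}

# Effective per-cluster prevalence matrix after applying the separation
# control on the logit scale, anchored at the mixture-weighted population mean.
effective_prevalence <- function(spec) {
  P <- spec$condition_prevalence
  if (spec$separation == 1) return(P)
  w <- spec$mixing_weights
  p_pop <- as.numeric(w %*% P)
  eps <- 1e-9
  lp <- logit(pmin(pmax(P, eps), 1 - eps))
  lpop <- logit(pmin(pmax(p_pop, eps), 1 - eps))
  out <- inv_logit(sweep(sweep(lp, 2, lpop, "-") * spec$separation, 2, lpop, "+"))
  # exact 0/1 prevalences are kept exact at any separation > 0
  if (spec$separation > 0) {
    out[P == 0] <- 0
    out[P == 1] <- 1
  }
  dimnames(out) <- dimnames(P)
  out
}

#' Bundled six-cluster fixture specification
#'
#' A fixed `cohort_spec` used throughout the documentation and tests. Its
#' six planted clusters echo the subgroup structure repeatedly reported for
#' high-cost high-need Medicaid adults: a relatively healthy group, a
#' pregnancy-complications group (condition prevalence 0.98), a behavioral
#' health group (high mental-illness and neurologic prevalence), a
#' cardio-metabolic group (high endocrine and cardiovascular prevalence),
#' and two multimorbid "complex illness" groups with lower and higher
#' resource use. Demographic and utilization parameters follow the same
#' published per-cluster pattern (mean ages 28-54, a 100%-female pregnancy
#' cluster, admission means 0.3-2.0, ED means 2.9-14.6, preventable
#' utilization well below its parent counts).
#'
#' @param n_patients Cohort size (default 3000, a desk-scale stand-in for
#'   the six-figure populations these analyses run on).
#' @param separation Planted-separation multiplier (see [cohort_spec()]);
#'   `1` keeps the stated prevalences, `3` is the "high separation" regime
#'   used for parameter-recovery checks.
#' @param seed Integer seed.
#'
#' @return A `cohort_spec` with 6 clusters and 12 condition categories.
#' @export
fixture_cohort_spec <- function(n_patients = 3000, separation = 1, seed = 1) {
  cats <- c("PREG", "MENTAL", "SUBST", "NEURO", "ENDO", "CARDIO",
            "RESP", "MUSCULO", "GI", "GU", "INJURY", "SCREEN")
  # rows: RelativelyHealthy, PregnancyComplications, BehavioralHealth,
  #       CardioMetabolic, ComplexLow, ComplexHigh
  P <- rbind(
    c(0.02, 0.10, 0.05, 0.08, 0.10, 0.12, 0.10, 0.10, 0.08, 0.06, 0.10, 0.60),
    c(0.98, 0.12, 0.05, 0.05, 0.08, 0.05, 0.06, 0.05, 0.08, 0.40, 0.05, 0.50),
    c(0.03, 0.90, 0.65, 0.86, 0.12, 0.15, 0.15, 0.15, 0.12, 0.08, 0.40, 0.35),
    c(0.02, 0.15, 0.08, 0.12, 0.96, 0.93, 0.20, 0.20, 0.15, 0.35, 0.10, 0.40),
    c(0.02, 0.12, 0.10, 0.30, 0.50, 0.55, 0.75, 0.70, 0.65, 0.20, 0.20, 0.45),
    c(0.03, 0.50, 0.25, 0.60, 0.80, 0.85, 0.80, 0.80, 0.80, 0.75, 0.70, 0.50)
  )
  colnames(P) <- cats

  demographics <- tibble::tibble(
    age_mean = c(42, 28, 40, 51, 54, 52),
    age_sd   = c(13, 6, 12, 12, 12, 12),
    p_female = c(0.61, 1.00, 0.84, 0.45, 0.68, 0.65)
  )

  elig <- rbind(
    c(58, 34, 6, 2), c(95, 4, 1, 0), c(58, 35, 6, 1),
    c(34, 54, 8, 4), c(41, 47, 6, 6), c(26, 61, 6, 7)
  )
  elig <- elig / rowSums(elig)
  colnames(elig) <- eligibility_levels()

  race <- rbind(
    c(50, 23, 6, 3, 2, 16), c(48, 27, 9, 4, 1, 11), c(62, 17, 5, 1, 2, 13),
    c(50, 21, 5, 4, 1, 19), c(38, 21, 10, 8, 2, 21), c(49, 18, 5, 2, 1, 25)
  )
  race <- race / rowSums(race)
  colnames(race) <- race_levels()

  utilization <- tibble::tibble(
    adm_mean   = c(0.3, 0.8, 0.4, 0.4, 0.5, 2.0),
    adm_sd     = c(2.3, 0.6, 1.2, 1.7, 1.5, 3.3),
    days_mean  = c(4.3, 2.5, 2.1, 2.8, 3.2, 16.0),
    ed_mean    = c(2.9, 4.7, 7.9, 4.8, 4.9, 14.6),
    ed_sd      = c(6.1, 6.2, 12.6, 8.5, 8.4, 26.7),
    # thinning probabilities = preventable mean / parent mean per cluster
    p_prev_adm = c(0.01, 0.02, 0.04, 0.06, 0.10, 0.33) /
                 c(0.3, 0.8, 0.4, 0.4, 0.5, 2.0),
    p_prev_ed  = c(1.1, 1.9, 2.9, 1.9, 2.4, 6.3) /
                 c(2.9, 4.7, 7.9, 4.8, 4.9, 14.6)
  )

  cohort_spec(
    n_patients = n_patients,
    mixing_weights = c(100247, 63329, 80760, 94135, 77871, 67985) / 484327,
    condition_prevalence = P,
    demographics = demographics,
    eligibility_prob = elig,
    race_prob = race,
    utilization = utilization,
    separation = separation,
    seed = seed
  )
}

#' Four-cluster stability demonstration specification
#'
#' A small `cohort_spec` designed to exhibit a stability gradient: clusters
#' 1 and 2 have disjoint, near-deterministic condition profiles (well
#' separated), while clusters 3 and 4 share most of their condition
#' prevalences (heavily overlapping). Demographics are identical across
#' clusters so condition patterns alone drive the clustering, and bootstrap
#' stability indices for clusters 1-2 should clearly exceed those for 3-4.
#'
#' @param n_patients Cohort size (default 800).
#' @param seed Integer seed.
#' @return A `cohort_spec` with 4 clusters and 8 condition categories.
#' @export
stability_demo_spec <- function(n_patients = 800, seed = 1) {
  cats <- paste0("C", 1:8)
  P <- rbind(
    c(0.95, 0.95, 0.03, 0.03, 0.05, 0.05, 0.05, 0.05),
    c(0.03, 0.03, 0.95, 0.95, 0.05, 0.05, 0.05, 0.05),
    c(0.05, 0.05, 0.05, 0.05, 0.55, 0.55, 0.45, 0.45),
    c(0.05, 0.05, 0.05, 0.05, 0.45, 0.45, 0.55, 0.55)
  )
  colnames(P) <- cats
  demo <- tibble::tibble(age_mean = rep(45, 4), age_sd = rep(12, 4),
                         p_female = rep(0.6, 4))
  elig <- matrix(rep(c(0.5, 0.4, 0.07, 0.03), each = 4), nrow = 4,
                 dimnames = list(NULL, eligibility_levels()))
  race <- matrix(rep(c(0.5, 0.2, 0.08, 0.04, 0.01, 0.17), each = 4), nrow = 4,
                 dimnames = list(NULL, race_levels()))
  util <- tibble::tibble(adm_mean = rep(0.6, 4), adm_sd = rep(1.5, 4),
                         days_mean = rep(3, 4), ed_mean = rep(5, 4),
                         ed_sd = rep(8, 4), p_prev_adm = rep(0.1, 4),
                         p_prev_ed = rep(0.4, 4))
  cohort_spec(
    n_patients = n_patients,
    mixing_weights = rep(0.25, 4),
    condition_prevalence = P,
    demographics = demo,
    eligibility_prob = elig,
    race_prob = race,
    utilization = util,
    seed = seed
  )
}
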