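#' Encoding scheme for mixed patient-year features
#'
#' Describes how each clustering input enters the feature matrix:
#' continuous variables are z-scored against the cohort; every categorical
#' variable (including binary indicators) is mapped to a point on the unit
#' circle so that it can enter a Euclidean clustering with bounded,
#' symmetric per-variable influence. Utilization and spend variables are
#' never part of a scheme: clusters are defined by demographics and
#' condition patterns only, so utilization comparisons between clusters
#' remain unbiased.
#'
#' The level ordering of each categorical variable determines its polar
#' angles and is an explicit configuration choice.
#'
#' @param patient_years Patient-year tibble used to auto-detect condition
#'   flag columns (`cond_*`).
#' @param continuous Character vector of continuous variables (default
#'   `"age"`).
#' @param binary Character vector of 0/1 variables; defaults to `female`
#'   plus every `cond_*` column.
#' @param categorical Named list of level orderings for multi-level
#'   variables; defaults to the eligibility-program and race/ethnicity
#'   vocabularies.
#' @return An object of class `encoding_scheme`.
#' @export
encoding_scheme <- function(patient_years,
                            continuous = "age",
                            binary = NULL,
                            categorical = NULL) {
  binary <- binary %||% c("female", grep("^cond_", names(patient_years), value = TRUE))
  categorical <- categorical %||% list(eligibility = eligibility_levels(),
                                       race_ethnicity = race_levels())
  vars <- c(continuous, binary, names(categorical))
  forbidden <- intersect(vars, utilization_variables())
  if (length(forbidden) > 0) {
    abort(paste0("utilization/spend variables may not enter the feature matrix: ",
                 paste(forbidden, collapse = ", ")))
  }
  if (anyDuplicated(vars)) abort("a variable appears in more than one encoding role.")
  structure(list(continuous = continuous, binary = binary,
                 categorical = categorical),
            class = "encoding_scheme")
}

utilization_variables <- function() {
  c("admissions", "hospital_days", "ed_visits",
    "preventable_admissions", "preventable_ed_visits", "annual_spend")
}

#' Encode patient-year records as a numeric feature matrix
#'
#' Builds the n x p matrix fed to k-means. A categorical variable with L
#' ordered levels maps its 1-based level l to the angle
#' `theta = 2*pi*(l-1)/L` and emits the column pair
#' `(cos(theta), sin(theta))`; every pair therefore lies exactly on the
#' unit circle and contributes at most squared distance 4 between any two
#' patients. Binary indicators use the quarter-circle convention
#' `0 -> (1, 0)`, `1 -> (0, 1)` (disagreement distance sqrt(2)).
#' Continuous variables are z-scored against the cohort. Per-column
#' metadata traces every coordinate back to its source variable.
#'
#' @param patient_years Patient-year tibble.
#' @param scheme An [encoding_scheme()]; defaults to
#'   `encoding_scheme(patient_years)`.
#' @return An object of class `hcn_features`: list with `values` (numeric
#'   matrix), `column_meta` (tibble: column, source, role, levels), and
#'   `row_ids` (patient ids in row order).
#' @export
polar_encode <- function(patient_years, scheme = NULL) {
  scheme <- scheme %||% encoding_scheme(patient_years)
  py <- patient_years
  n <- nrow(py)
  cols <- list()
  meta <- list()

  for (v in scheme$continuous) {
    x <- py[[v]]
    if (is.null(x)) abort(sprintf("variable '%s' not found.", v))
    mu <- mean(x)
    s <- stats::sd(x)
    if (n <= 1 || is.na(s) || s == 0) {
      warn(sprintf("continuous variable '%s' has zero variance; encoded as 0.", v))
      z <- rep(0, n)
    } else {
      z <- (x - mu) / s
    }
    cols[[paste0(v, "_z")]] <- z
    meta[[length(meta) + 1]] <- tibble::tibble(
      column = paste0(v, "_z"), source = v, role = "scaled-continuous",
      levels = NA_character_)
  }

  add_polar <- function(theta, v, levels_str) {
    cols[[paste0(v, "_cos")]] <<- cos(theta)
    cols[[paste0(v, "_sin")]] <<- sin(theta)
    meta[[length(meta) + 1]] <<- tibble::tibble(
      column = paste0(v, c("_cos", "_sin")), source = v,
      role = c("polar-cos", "polar-sin"), levels = levels_str)
  }

  for (v in scheme$binary) {
    x <- py[[v]]
    if (is.null(x)) abort(sprintf("variable '%s' not found.", v))
    if (!all(x %in% c(0, 1))) {
      abort(sprintf("binary variable '%s' has values outside {0, 1}.", v))
    }
    # quarter-circle convention: 0 -> angle 0, 1 -> angle pi/2
    add_polar(ifelse(x == 1, pi / 2, 0), v, "0|1")
  }

  for (v in names(scheme$categorical)) {
    x <- py[[v]]
    if (is.null(x)) abort(sprintf("variable '%s' not found.", v))
    lev <- scheme$categorical[[v]]
    l <- match(as.character(x), lev)
    if (anyNA(l) && n > 0) {
      bad <- unique(as.character(x)[is.na(l)])
      abort(sprintf("variable '%s' has level(s) not in its encoding scheme: %s",
                    v, paste(bad, collapse = ", ")))
    }
    add_polar(2 * pi * (l - 1) / length(lev), v, paste(lev, collapse = "|"))
  }

  values <- do.call(cbind, cols)
  if (is.null(values)) values <- matrix(numeric(0), nrow = n, ncol = 0)
  meta <- dplyr::bind_rows(meta)
  bad <- intersect(meta$source, utilization_variables())
  if (length(bad) > 0) {
    abort("internal error: utilization variable leaked into the feature matrix.")
  }
  structure(list(values = values, column_meta = meta,
                 row_ids = py$patient_id %||% as.character(seq_len(n))),
            class = "hcn_features")
}

#' @export
print.hcn_features <- function(x, ...) {
  cat("<hcn_features>", nrow(x$values), "patients x", ncol(x$values),
      "columns (", sum(x$column_meta$role == "scaled-continuous"),
      "continuous,", sum(x$column_meta$role == "polar-cos"), "polar pairs )\n")
  invisible(x)
}

#' @export
as.matrix.hcn_features <- function(x, ...) x$values

# Accept either an hcn_features object or a bare numeric matrix/data frame.
feature_values <- function(features) {
  if (inherits(features, "hcn_features")) return(features$values)
  m <- as.matrix(features)
  storage.mode(m) <- "double"
  m
}

feature_row_ids <- function(features) {
  if (inherits(features, "hcn_features")) return(features$row_ids)
  rownames(features) %||% as.character(seq_len(nrow(features)))
}
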