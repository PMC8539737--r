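#' Per-cluster descriptive profiles
#'
#' Summarises every cluster over its assigned patients: size and share of
#' the cohort, demographics (mean age, % female, % by eligibility program
#' and race/ethnicity including Missing), condition-category prevalence
#' (%), and utilization (mean and SD of admissions, hospital days, ED
#' visits, preventable admissions, preventable ED visits, plus mean annual
#' spend). Utilization is summarised here even though it is excluded from
#' the clustering features, precisely so that between-cluster utilization
#' comparisons are unbiased by construction. Grand (cohort-level) values
#' and patient-level SDs are kept alongside for deviation scoring.
#'
#' @param patient_years Patient-year tibble.
#' @param assignments Integer cluster id per patient (same order), or an
#'   `hcn_kmeans` fit.
#' @return An object of class `hcn_profiles`: `clusters` (tibble, one row
#'   per cluster), `grand` (one-row tibble of cohort values),
#'   `grand_sd` (named vector of patient-level SDs of the clustering-input
#'   features), `features` (names of the clustering-input summary columns),
#'   `n`.
#' @export
profile_clusters <- function(patient_years, assignments) {
  if (inherits(assignments, "hcn_kmeans")) assignments <- assignments$assignments
  py <- patient_years
  n <- nrow(py)
  if (length(assignments) != n) abort("every patient must carry a cluster assignment.")

  wide <- profile_input_features(py)
  util <- c(admissions = "admissions", hospital_days = "hospital_days",
            ed_visits = "ed_visits",
            preventable_admissions = "preventable_admissions",
            preventable_ed_visits = "preventable_ed_visits")

  summarise_block <- function(df, wide_block) {
    out <- tibble::tibble(n = nrow(df))
    for (f in colnames(wide_block)) out[[f]] <- mean(wide_block[, f])
    for (u in util) {
      out[[paste0(u, "_mean")]] <- mean(df[[u]])
      out[[paste0(u, "_sd")]] <- stats::sd(df[[u]])
    }
    out$annual_spend_mean <- mean(df$annual_spend)
    out
  }

  ks <- sort(unique(assignments))
  clusters <- purrr::map_dfr(ks, function(cl) {
    idx <- assignments == cl
    dplyr::bind_cols(tibble::tibble(cluster = cl),
                     summarise_block(py[idx, , drop = FALSE],
                                     wide[idx, , drop = FALSE]))
  })
  n_total <- n
  clusters <- dplyr::mutate(clusters, share_pct = 100 * .data$n / n_total,
                            .after = "n")
  grand <- dplyr::bind_cols(tibble::tibble(cluster = NA_integer_),
                            summarise_block(py, wide))
  grand <- dplyr::mutate(grand, share_pct = 100, .after = "n")

  structure(list(clusters = clusters, grand = grand,
                 grand_sd = apply(wide, 2, stats::sd),
                 features = colnames(wide), n = n),
            class = "hcn_profiles")
}

# Patient-level numeric matrix of the clustering-input features, on the
# reporting scale: age in years, all indicators in percentage points.
profile_input_features <- function(py) {
  cols <- list(age = py$age, pct_female = 100 * py$female)
  for (lev in eligibility_levels()) {
    cols[[paste0("pct_elig_", gsub("[^A-Za-z]", "_", lev))]] <-
      100 * as.numeric(py$eligibility == lev)
  }
  for (lev in race_levels()) {
    cols[[paste0("pct_race_", lev)]] <- 100 * as.numeric(py$race_ethnicity == lev)
  }
  for (v in grep("^cond_", names(py), value = TRUE)) {
    cols[[paste0("prev_", sub("^cond_", "", v))]] <- 100 * py[[v]]
  }
  do.call(cbind, cols)
}

#' @export
print.hcn_profiles <- function(x, ...) {
  cat("<hcn_profiles>", nrow(x$clusters), "clusters over", x$n, "patients\n")
  print(dplyr::select(x$clusters, "cluster", "n", "share_pct",
                      dplyr::any_of(c("age", "pct_female"))))
  invisible(x)
}

#' Rank each cluster's maximally deviating features
#'
#' For every clustering-input feature the deviation score is
#' `(cluster mean - grand mean) / grand SD`, where the grand SD is the
#' patient-level cohort SD of the feature; scores are therefore scale-free
#' and comparable across age and percentage features. Features are ranked
#' by absolute score within each cluster; the sign says whether the cluster
#' sits above or below the cohort. Zero-variance features are excluded
#' (their score is undefined) and reported via the `excluded` attribute.
#'
#' @param profiles An `hcn_profiles` object.
#' @param top_m Number of top features per cluster (default 5).
#' @param min_abs Minimum absolute score to report (default 0).
#' @return Tibble: cluster, feature, cluster_value, grand_value, score,
#'   rank; attribute `excluded` lists zero-variance features.
#' @export
rank_deviations <- function(profiles, top_m = 5, min_abs = 0) {
  if (!inherits(profiles, "hcn_profiles")) abort("`profiles` must come from profile_clusters().")
  sds <- profiles$grand_sd
  excluded <- names(sds)[sds == 0 | is.na(sds)]
  usable <- setdiff(profiles$features, excluded)
  if (length(excluded) > 0) {
    message("rank_deviations: excluding zero-variance feature(s): ",
            paste(excluded, collapse = ", "))
  }
  grand_vec <- unlist(profiles$grand[, usable, drop = FALSE])
  out <- profiles$clusters |>
    dplyr::select("cluster", dplyr::all_of(usable)) |>
    tidyr::pivot_longer(-"cluster", names_to = "feature",
                        values_to = "cluster_value") |>
    dplyr::mutate(
      grand_value = unname(grand_vec[.data$feature]),
      score = (.data$cluster_value - .data$grand_value) /
        unname(sds[.data$feature])
    ) |>
    dplyr::filter(abs(.data$score) >= min_abs) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(dplyr::desc(abs(.data$score)), .data$feature,
                   .by_group = TRUE) |>
    dplyr::slice_head(n = top_m) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
  attr(out, "excluded") <- excluded
  out
}

#' Default cluster-naming rules
#'
#' An editable rule table mechanising the step "name the cluster after its
#' pattern of outlying features". Each rule has a regular expression over
#' feature names, a direction (`above` / `below` / `any` the grand mean),
#' the minimum number of top-deviation features that must match, an
#' optional minimum cluster value (on the reporting scale, e.g. prevalence
#' in %) for the matching features, and the label. Rules are tried in
#' order; the first match wins. Final naming remains a human decision —
#' rule-derived labels are suggestions and never override a user-supplied
#' label.
#'
#' @return Tibble: label, pattern, direction, min_matches, min_value.
#' @export
default_naming_rules <- function() {
  tibble::tribble(
    ~label,                   ~pattern,                        ~direction, ~min_matches, ~min_value,
    "Pregnancy Complications", "prev_PREG",                    "above",    1L,           90,
    "Behavioral Health",       "prev_(MENTAL|SUBST|NEURO)",    "above",    2L,           NA,
    "Cardio-metabolic",        "prev_(ENDO|CARDIO)",           "above",    2L,           NA,
    "Complex Illness",         "^prev_",                       "above",    3L,           NA,
    "Relatively Healthy",      "^prev_",                       "below",    3L,           NA
  )
}

#' Suggest a label for each cluster from its top deviations
#'
#' Applies [default_naming_rules()]-style rules to the ranked deviations of
#' each cluster. When no rule matches, the fallback label is
#' `"Cluster <id>: <top feature>"` (or just `"Cluster <id>"` if the cluster
#' has no reported deviations). User-supplied labels always win.
#'
#' @param top_deviations Output of [rank_deviations()].
#' @param naming_rules Rule table (default [default_naming_rules()]).
#' @param user_labels Optional named character vector (names = cluster
#'   ids) of labels that override any rule.
#' @return Tibble: cluster, label, source (`"user"`, `"rule"`,
#'   `"fallback"`).
#' @export
suggest_label <- function(top_deviations, naming_rules = default_naming_rules(),
                          user_labels = NULL) {
  purrr::map_dfr(sort(unique(top_deviations$cluster)), function(cl) {
    if (!is.null(user_labels) && as.character(cl) %in% names(user_labels)) {
      return(tibble::tibble(cluster = cl,
                            label = unname(user_labels[as.character(cl)]),
                            source = "user"))
    }
    td <- top_deviations[top_deviations$cluster == cl, , drop = FALSE]
    for (i in seq_len(nrow(naming_rules))) {
      r <- naming_rules[i, ]
      hit <- stringr::str_detect(td$feature, r$pattern)
      hit <- hit & switch(r$direction,
                          above = td$score > 0,
                          below = td$score < 0,
                          any = TRUE)
      if (!is.na(r$min_value)) hit <- hit & td$cluster_value >= r$min_value
      if (sum(hit) >= r$min_matches) {
        return(tibble::tibble(cluster = cl, label = r$label, source = "rule"))
      }
    }
    top_feature <- if (nrow(td) > 0) td$feature[td$rank == 1][1] else NA_character_
    label <- if (is.na(top_feature)) paste0("Cluster ", cl) else
      paste0("Cluster ", cl, ": ", top_feature)
    tibble::tibble(cluster = cl, label = label, source = "fallback")
  })
}

#' Condition-prevalence heat-map table
#'
#' The condition-category x cluster matrix of prevalences (%) behind the
#' usual cluster heat map, as a tidy tibble with one row per category and
#' one `cluster_<id>` column per cluster.
#'
#' @param profiles An `hcn_profiles` object.
#' @param category_order Optional character vector ordering the categories
#'   (names without the `prev_` prefix).
#' @return A tibble: `category` plus one column per cluster.
#' @export
export_heatmap_table <- function(profiles, category_order = NULL) {
  if (!inherits(profiles, "hcn_profiles")) abort("`profiles` must come from profile_clusters().")
  prev_cols <- grep("^prev_", profiles$features, value = TRUE)
  if (length(prev_cols) == 0) abort("profiles contain no condition-prevalence features.")
  tab <- profiles$clusters |>
    dplyr::select("cluster", dplyr::all_of(prev_cols)) |>
    tidyr::pivot_longer(-"cluster", names_to = "category", values_to = "prevalence") |>
    dplyr::mutate(category = sub("^prev_", "", .data$category)) |>
    tidyr::pivot_wider(names_from = "cluster", values_from = "prevalence",
                       names_prefix = "cluster_")
  if (!is.null(category_order)) {
    tab <- tab[match(category_order, tab$category), , drop = FALSE]
  }
  tab
}
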