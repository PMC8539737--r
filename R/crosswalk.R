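#' Condition crosswalks and preventable-utilization flag tables
#'
#' Diagnosis grouping is driven by a user-supplied crosswalk table mapping
#' ICD-9-CM code prefixes to condition categories at one or more levels,
#' mirroring the shape of multi-level clinical classification systems
#' without bundling any licensed content. Preventable utilization is driven
#' by a second prefix table flagging codes by care setting (IP for
#' preventable hospitalizations, ED for preventable emergency visits),
#' standing in for licensed prevention-quality / ED-classification
#' algorithms as a pluggable code-to-flag table.
#'
#' @name crosswalks
NULL

#' Bundled synthetic condition crosswalk
#'
#' A small, fully synthetic crosswalk covering the 12 condition categories
#' used by [fixture_cohort_spec()]. Prefixes are ICD-9-CM-flavored but the
#' table is invented for testing and documentation; it is not the licensed
#' AHRQ CCS. Categories are defined at level 2 (the grouping level used for
#' clustering) with a coarser level-1 rollup to exercise multi-level
#' handling.
#'
#' @return A tibble with columns `code_prefix`, `category_id`,
#'   `category_name`, `level`.
#' @export
synthetic_ccs_crosswalk <- function() {
  l2 <- list(
    PREG    = list(name = "Pregnancy & childbirth complications", prefixes = c("64", "65")),
    MENTAL  = list(name = "Mental illness", prefixes = c("295", "296", "300", "311")),
    SUBST   = list(name = "Substance use disorders", prefixes = c("303", "304", "305")),
    NEURO   = list(name = "Neurologic disorders", prefixes = c("340", "345", "348")),
    ENDO    = list(name = "Endocrine & metabolic disorders", prefixes = c("250", "272")),
    CARDIO  = list(name = "Cardiovascular disease", prefixes = c("401", "410", "414", "428")),
    RESP    = list(name = "Respiratory disease", prefixes = c("486", "491", "493")),
    MUSCULO = list(name = "Musculoskeletal disorders", prefixes = c("714", "715", "724")),
    GI      = list(name = "Gastrointestinal disorders", prefixes = c("530", "558", "571")),
    GU      = list(name = "Genitourinary & renal disorders", prefixes = c("585", "590", "599")),
    INJURY  = list(name = "Injury & poisoning", prefixes = c("820", "850", "965")),
    SCREEN  = list(name = "Screening & residual codes", prefixes = c("V70", "780"))
  )
  l1 <- list(
    PREG_L1   = list(name = "Complications of pregnancy (L1)", prefixes = c("64", "65")),
    MENTAL_L1 = list(name = "Mental disorders (L1)", prefixes = c("29", "30", "31")),
    NERV_L1   = list(name = "Nervous system (L1)", prefixes = "34"),
    ENDO_L1   = list(name = "Endocrine & metabolic (L1)", prefixes = c("25", "27")),
    CIRC_L1   = list(name = "Circulatory system (L1)", prefixes = c("40", "41", "42")),
    RESP_L1   = list(name = "Respiratory system (L1)", prefixes = c("48", "49")),
    MUSC_L1   = list(name = "Musculoskeletal system (L1)", prefixes = c("71", "72")),
    DIG_L1    = list(name = "Digestive system (L1)", prefixes = c("53", "55", "57")),
    GU_L1     = list(name = "Genitourinary system (L1)", prefixes = c("58", "59")),
    INJ_L1    = list(name = "Injury & poisoning (L1)", prefixes = c("82", "85", "96")),
    RESID_L1  = list(name = "Residual & screening (L1)", prefixes = c("V7", "78"))
  )
  build <- function(defs, level) {
    purrr::imap_dfr(defs, function(d, id) {
      tibble::tibble(code_prefix = d$prefixes, category_id = id,
                     category_name = d$name, level = level)
    })
  }
  xw <- dplyr::bind_rows(build(l2, "2"), build(l1, "1"))
  validate_crosswalk(xw)
}

#' Bundled synthetic preventable-utilization flag table
#'
#' Synthetic stand-in for licensed preventable-utilization classifications:
#' code prefixes flagged as possibly preventable when they appear as the
#' principal diagnosis of an inpatient stay (`setting = "IP"`) or an
#' emergency visit (`setting = "ED"`).
#'
#' @return A tibble with columns `code_prefix`, `setting`.
#' @export
synthetic_preventable_flags <- function() {
  ed <- c("643.0", "300.0", "305.0", "345.9", "250.1", "401.9", "493.90",
          "724.5", "558.9", "599.0", "965.0", "780.60", "799.01")
  ip <- c("646.6", "296.8", "303.9", "348.1", "250.8", "428.0", "493.91",
          "714.0", "530.1", "590.80", "850.0", "780.97", "799.02")
  tibble::tibble(
    code_prefix = c(ed, ip),
    setting = rep(c("ED", "IP"), c(length(ed), length(ip)))
  )
}

# Per-category ICD-9-flavored code pool used when synthesising claim lines.
# `plain` codes are never matched by the preventable-flag table; `ed_prev`
# and `ip_prev` codes are flagged in the corresponding setting. The `.filler`
# family is deliberately absent from the crosswalk (exercises unmapped-code
# accounting) and is used for encounters of patients with no active
# condition category.
synthetic_code_pool <- function() {
  list(
    PREG    = list(plain = c("642.0", "648.9"), ed_prev = "643.0",  ip_prev = "646.6"),
    MENTAL  = list(plain = c("295.3", "296.2"), ed_prev = "300.0",  ip_prev = "296.8"),
    SUBST   = list(plain = c("304.2", "305.5"), ed_prev = "305.0",  ip_prev = "303.9"),
    NEURO   = list(plain = c("340", "348.9"),   ed_prev = "345.9",  ip_prev = "348.1"),
    ENDO    = list(plain = c("250.00", "272.4"), ed_prev = "250.13", ip_prev = "250.80"),
    CARDIO  = list(plain = c("410.9", "414.0"), ed_prev = "401.9",  ip_prev = "428.0"),
    RESP    = list(plain = c("486", "491.21"),  ed_prev = "493.90", ip_prev = "493.91"),
    MUSCULO = list(plain = c("715.9", "724.2"), ed_prev = "724.5",  ip_prev = "714.0"),
    GI      = list(plain = c("530.81", "571.5"), ed_prev = "558.9", ip_prev = "530.10"),
    GU      = list(plain = c("585.6", "599.7"), ed_prev = "599.0",  ip_prev = "590.80"),
    INJURY  = list(plain = c("820.8", "850.9"), ed_prev = "965.09", ip_prev = "850.0"),
    SCREEN  = list(plain = c("V70.0", "780.79"), ed_prev = "780.60", ip_prev = "780.97"),
    .filler = list(plain = "799.3", ed_prev = "799.01", ip_prev = "799.02")
  )
}

validate_crosswalk <- function(crosswalk) {
  crosswalk <- tibble::as_tibble(crosswalk)
  need <- c("code_prefix", "category_id", "category_name", "level")
  if (!all(need %in% names(crosswalk))) {
    abort(paste0("crosswalk must have columns ", paste(need, collapse = ", "), "."))
  }
  crosswalk$level <- as.character(crosswalk$level)
  dup <- crosswalk |>
    dplyr::count(.data$level, .data$code_prefix) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("crosswalk maps prefix '%s' to multiple categories at level %s.",
                  dup$code_prefix[1], dup$level[1]))
  }
  crosswalk
}

#' Read a condition crosswalk or preventable-flag table from CSV
#'
#' `read_crosswalk()` expects columns `code_prefix`, `category_id`,
#' `category_name`, `level`; `read_preventable_flags()` expects
#' `code_prefix`, `setting` with settings in `IP`, `ED`. Wildcarding is by
#' code prefix: an entry matches every code that starts with it, and when
#' several entries match the same code at the same level the longest prefix
#' wins.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_crosswalk <- function(path) {
  xw <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  validate_crosswalk(xw)
}

#' @rdname read_crosswalk
#' @export
read_preventable_flags <- function(path) {
  fl <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("code_prefix", "setting") %in% names(fl))) {
    abort("preventable-flag table must have columns code_prefix, setting.")
  }
  if (!all(fl$setting %in% c("IP", "ED"))) {
    abort("preventable-flag settings must be 'IP' or 'ED'.")
  }
  tibble::as_tibble(fl)
}

# Longest-prefix category lookup. Returns the category_id for each code at
# the given level, NA_character_ where no prefix matches.
match_categories <- function(codes, crosswalk, level = "2") {
  xw <- crosswalk[crosswalk$level == level, , drop = FALSE]
  if (nrow(xw) == 0) abort(sprintf("crosswalk has no entries at level '%s'.", level))
  ucodes <- unique(codes)
  hit <- rep(NA_character_, length(ucodes))
  hit_len <- rep(-1L, length(ucodes))
  ord <- order(nchar(xw$code_prefix))  # longer prefixes processed last win
  for (i in ord) {
    m <- startsWith(ucodes, xw$code_prefix[i])
    hit[m] <- xw$category_id[i]
    hit_len[m] <- nchar(xw$code_prefix[i])
  }
  hit[match(codes, ucodes)]
}

# Prefix match against a preventable-flag table for one setting.
match_flagged <- function(codes, preventable_map, setting) {
  prefixes <- preventable_map$code_prefix[preventable_map$setting == setting]
  if (length(prefixes) == 0) return(rep(FALSE, length(codes)))
  ucodes <- unique(codes)
  hit <- rep(FALSE, length(ucodes))
  for (p in prefixes) hit <- hit | startsWith(ucodes, p)
  hit[match(codes, ucodes)]
}

# Ordered category ids at a crosswalk level (order of first appearance).
crosswalk_categories <- function(crosswalk, level = "2") {
  unique(crosswalk$category_id[crosswalk$level == level])
}
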