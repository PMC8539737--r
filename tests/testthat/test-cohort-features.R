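py_with_spend <- function(spend, age = 30) {
  tibble::tibble(patient_id = paste0("S", seq_along(spend)),
                 age = age, annual_spend = spend)
}

test_that("eligibility selection follows rank arithmetic and the tie rule", {
  py <- py_with_spend(1:100)
  sel <- select_eligible(py, quantile = 0.05)
  expect_setequal(sel$annual_spend, 96:100)

  sel1 <- select_eligible(py_with_spend(1:20), quantile = 0.05)
  expect_identical(sel1$annual_spend, 20L)

  # ties at the boundary are all included
  tied <- py_with_spend(c(1, 2, 3, rep(10, 3), 11, rep(5, 13)))
  sel_t <- select_eligible(tied, quantile = 0.10)  # top 2 by rank, 10 is tied
  expect_setequal(sel_t$annual_spend, c(10, 10, 10, 11))
})

test_that("eligibility selection equals the sort-and-slice oracle", {
  spend <- withr::with_seed(7, exp(rnorm(1000, 8, 1.2)))
  py <- py_with_spend(spend)
  sel <- select_eligible(py, quantile = 0.05)
  oracle_ids <- py$patient_id[order(spend, decreasing = TRUE)][1:50]
  expect_setequal(sel$patient_id, oracle_ids)
})

test_that("eligibility applies the adult-age filter and flags degenerate input", {
  py <- py_with_spend(1:100, age = rep(c(18, 40), 50))
  sel <- select_eligible(py, quantile = 0.10)
  expect_true(all(sel$age >= 21))
  # quantile computed among adults only: top 5 of the 50 adults
  expect_identical(nrow(sel), 5L)
  expect_error(select_eligible(py[0, ]), "empty")
  expect_error(select_eligible(py_with_spend(rep(5, 30))), "tie policy")
  expect_error(select_eligible(py, quantile = 1.2), "probability")
})

test_that("condition grouping matches direct lookup and handles wildcards", {
  xw <- synthetic_ccs_crosswalk()
  claims <- tibble::tibble(
    patient_id = c("A", "A", "B"),
    service_date = as.Date("2013-06-01"),
    setting = "OP",
    icd9 = c("250.00", "401.9", "999.99"),
    paid_amount = 10
  )
  flags <- group_conditions(claims, xw, patient_ids = c("A", "B", "C"),
                            quiet = TRUE)
  expect_identical(flags$cond_ENDO, c(1L, 0L, 0L))
  expect_identical(flags$cond_CARDIO, c(1L, 0L, 0L))
  expect_true(all(flags$cond_PREG == 0L))
  expect_identical(attr(flags, "unmapped")[["lines"]], 1L)
  # zero-claims patient C has an all-zero flag vector
  expect_true(all(unlist(flags[flags$patient_id == "C", -1]) == 0L))
})

test_that("longest prefix wins when nested prefixes match the same code", {
  xw <- tibble::tibble(
    code_prefix = c("250", "250.1"),
    category_id = c("DIAB", "DIAB_COMP"),
    category_name = c("Diabetes", "Diabetes with complications"),
    level = "2"
  )
  claims <- tibble::tibble(patient_id = c("A", "B"),
                           service_date = as.Date("2013-01-01"),
                           setting = "OP", icd9 = c("250.00", "250.13"),
                           paid_amount = 0)
  flags <- group_conditions(claims, xw, quiet = TRUE)
  expect_identical(flags$cond_DIAB, c(1L, 0L))
  expect_identical(flags$cond_DIAB_COMP, c(0L, 1L))
})

test_that("condition grouping equals a naive per-claim scan on random claims", {
  xw <- synthetic_ccs_crosswalk()
  pool <- getFromNamespace("synthetic_code_pool", "hcnseg")()
  codes <- unlist(lapply(pool, unlist), use.names = FALSE)
  claims <- withr::with_seed(11, tibble::tibble(
    patient_id = sample(paste0("P", 1:40), 500, replace = TRUE),
    service_date = as.Date("2013-01-01"),
    setting = sample(c("IP", "ED", "OP"), 500, replace = TRUE),
    icd9 = sample(codes, 500, replace = TRUE),
    paid_amount = 0
  ))
  ids <- sort(unique(claims$patient_id))
  flags <- group_conditions(claims, xw, patient_ids = ids, quiet = TRUE)

  # naive double loop over patients and level-2 crosswalk entries
  xw2 <- xw[xw$level == "2", ]
  cats <- unique(xw2$category_id)
  naive <- matrix(0L, length(ids), length(cats),
                  dimnames = list(ids, cats))
  for (r in seq_len(nrow(claims))) {
    best_len <- -1L
    best_cat <- NA_character_
    for (e in seq_len(nrow(xw2))) {
      pfx <- xw2$code_prefix[e]
      if (startsWith(claims$icd9[r], pfx) && nchar(pfx) > best_len) {
        best_len <- nchar(pfx)
        best_cat <- xw2$category_id[e]
      }
    }
    if (!is.na(best_cat)) naive[claims$patient_id[r], best_cat] <- 1L
  }
  for (cat in cats) {
    expect_identical(flags[[paste0("cond_", cat)]], unname(naive[, cat]),
                     label = paste("category", cat))
  }
})

test_that("preventable flags count flagged principal codes per setting", {
  fl <- synthetic_preventable_flags()
  claims <- tibble::tibble(
    patient_id = rep("A", 4),
    service_date = as.Date("2013-01-01"),
    setting = c("ED", "ED", "ED", "IP"),
    icd9 = c("599.0", "599.0", "585.6", "428.0"),
    paid_amount = 0
  )
  out <- flag_preventable(claims, fl)
  expect_identical(out$preventable_ed_visits, 2L)
  expect_identical(out$preventable_admissions, 1L)
  # an empty flag map yields zeros
  empty <- flag_preventable(claims, fl[0, ])
  expect_true(all(empty$preventable_admissions == 0L))
  expect_true(all(empty$preventable_ed_visits == 0L))
})

test_that("preventable counts match a naive scan on a random cohort", {
  coh <- generate_cohort(fixture_cohort_spec(n_patients = 120, seed = 17))
  fl <- synthetic_preventable_flags()
  out <- flag_preventable(coh$claims, fl,
                          patient_ids = coh$patient_years$patient_id)
  hit <- function(codes, setting) {
    vapply(codes, function(cd) {
      any(startsWith(cd, fl$code_prefix[fl$setting == setting]))
    }, logical(1))
  }
  naive <- sapply(coh$patient_years$patient_id, function(id) {
    sub <- coh$claims[coh$claims$patient_id == id, ]
    c(ip = sum(sub$setting == "IP" & hit(sub$icd9, "IP")),
      ed = sum(sub$setting == "ED" & hit(sub$icd9, "ED")))
  })
  expect_identical(out$preventable_admissions, unname(naive["ip", ]))
  expect_identical(out$preventable_ed_visits, unname(naive["ed", ]))
})
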