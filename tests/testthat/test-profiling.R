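test_that("a single cluster's profile equals the cohort grand means", {
  py <- hand_cohort()
  pr <- profile_clusters(py, rep(1L, 6))
  expect_identical(nrow(pr$clusters), 1L)
  expect_equal(pr$clusters$share_pct, 100)
  row <- pr$clusters
  expect_equal(row$age, mean(py$age))
  expect_equal(row$pct_female, 100 * mean(py$female))
  expect_equal(row$prev_PREG, 100 * mean(py$cond_PREG))
  expect_equal(row$ed_visits_mean, mean(py$ed_visits))
  expect_equal(row$admissions_sd, sd(py$admissions))
  expect_equal(dplyr::select(row, -"cluster"),
               dplyr::select(pr$grand, -"cluster"),
               tolerance = 1e-12)
})

test_that("two-cluster profiles match hand computation", {
  py <- hand_cohort()
  cl <- c(1L, 1L, 2L, 1L, 2L, 2L)
  pr <- profile_clusters(py, cl)
  c1 <- pr$clusters[pr$clusters$cluster == 1, ]
  expect_equal(c1$n, 3L)
  expect_equal(c1$age, mean(c(30, 40, 20)))
  expect_equal(c1$pct_female, 100)
  expect_equal(c1$prev_PREG, 100)
  expect_equal(c1$prev_CARDIO, 0)
  expect_equal(c1$pct_elig_TANF, 100 * 2 / 3)
  expect_equal(c1$ed_visits_mean, 3)
  expect_equal(c1$preventable_ed_visits_mean, mean(c(1, 2, 1)))
  c2 <- pr$clusters[pr$clusters$cluster == 2, ]
  expect_equal(c2$admissions_mean, 2)
  expect_equal(c2$annual_spend_mean, mean(c(9000, 20000, 4000)))
})

test_that("weighted cluster means recompose the grand mean exactly", {
  coh <- generate_cohort(fixture_cohort_spec(n_patients = 500, seed = 12),
                         make_claims = FALSE)
  m <- fit_kmeans(polar_encode(coh$patient_years), 6, seed = 1, n_restarts = 4)
  pr <- profile_clusters(coh$patient_years, m$assignments)
  w <- pr$clusters$n / pr$n
  for (f in c(pr$features, "ed_visits_mean", "admissions_mean",
              "annual_spend_mean")) {
    expect_equal(sum(w * pr$clusters[[f]]), pr$grand[[f]], tolerance = 1e-9,
                 label = paste("recomposition of", f))
  }
  expect_equal(sum(pr$clusters$share_pct), 100, tolerance = 1e-9)
  prev_cols <- grep("^prev_", pr$features, value = TRUE)
  expect_true(all(unlist(pr$clusters[prev_cols]) >= 0 &
                    unlist(pr$clusters[prev_cols]) <= 100))
})

test_that("a merged pair of clusters profiles as the weighted combination", {
  py <- hand_cohort()
  pr3 <- profile_clusters(py, c(1L, 1L, 2L, 3L, 2L, 3L))
  pr2 <- profile_clusters(py, c(1L, 1L, 2L, 2L, 2L, 2L))  # merge 2 and 3
  a <- pr3$clusters[pr3$clusters$cluster == 2, ]
  b <- pr3$clusters[pr3$clusters$cluster == 3, ]
  merged <- pr2$clusters[pr2$clusters$cluster == 2, ]
  for (f in c("age", "pct_female", "prev_PREG", "ed_visits_mean")) {
    expect_equal(merged[[f]], (a$n * a[[f]] + b$n * b[[f]]) / (a$n + b$n),
                 tolerance = 1e-12)
  }
})

test_that("deviation scores follow the standardized-difference formula", {
  coh <- generate_cohort(fixture_cohort_spec(n_patients = 400, seed = 14),
                         make_claims = FALSE)
  pr <- profile_clusters(coh$patient_years, coh$true_labels)
  dev <- rank_deviations(pr, top_m = 50)
  # spot-check the formula on the pregnancy cluster
  row <- dev[dev$cluster == 2 & dev$feature == "prev_PREG", ]
  grand <- pr$grand$prev_PREG
  sd_p <- pr$grand_sd[["prev_PREG"]]
  expect_equal(row$score, (row$cluster_value - grand) / sd_p)
  expect_gt(row$score, 1)
  expect_identical(row$rank, 1L)  # pregnancy dominates its cluster
  # antisymmetry: clusters below the grand mean get negative scores
  low <- dev[dev$cluster == 1 & dev$feature == "prev_PREG", ]
  expect_lt(low$score, 0)
})

test_that("scores at the grand mean are zero and vanish above any threshold", {
  py <- hand_cohort()
  pr <- profile_clusters(py, rep(1L, 6))  # single cluster == grand mean
  dev0 <- suppressMessages(rank_deviations(pr))
  expect_true(all(dev0$score == 0))
  dev <- suppressMessages(rank_deviations(pr, min_abs = 0.01))
  expect_identical(nrow(dev), 0L)
})

test_that("deviation ranking is invariant to affine rescaling of age", {
  coh <- generate_cohort(fixture_cohort_spec(n_patients = 300, seed = 15),
                         make_claims = FALSE)
  py <- coh$patient_years
  pr1 <- rank_deviations(profile_clusters(py, coh$true_labels), top_m = 100)
  py$age <- py$age * 12L  # age in months
  pr2 <- rank_deviations(profile_clusters(py, coh$true_labels), top_m = 100)
  a1 <- pr1[pr1$feature == "age", c("cluster", "score")]
  a2 <- pr2[pr2$feature == "age", c("cluster", "score")]
  expect_equal(a1$score, a2$score, tolerance = 1e-9)
})

test_that("zero-variance features are excluded from ranking with a note", {
  py <- hand_cohort()
  py$cond_PREG <- 1L  # constant
  pr <- profile_clusters(py, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_message(dev <- rank_deviations(pr), "zero-variance")
  expect_false("prev_PREG" %in% dev$feature)
  expect_true("prev_PREG" %in% attr(dev, "excluded"))
})

test_that("naming rules label archetypal clusters and fall back gracefully", {
  coh <- generate_cohort(fixture_cohort_spec(n_patients = 2000, seed = 16),
                         make_claims = FALSE)
  pr <- profile_clusters(coh$patient_years, coh$true_labels)
  dev <- rank_deviations(pr)
  lab <- suggest_label(dev)
  expect_identical(lab$label[lab$cluster == 2], "Pregnancy Complications")
  expect_identical(lab$label[lab$cluster == 3], "Behavioral Health")
  expect_identical(lab$label[lab$cluster == 4], "Cardio-metabolic")
  expect_identical(lab$label[lab$cluster == 1], "Relatively Healthy")
  expect_true(all(lab$label[lab$cluster %in% c(5, 6)] == "Complex Illness"))

  # user labels always win
  lab2 <- suggest_label(dev, user_labels = c(`2` = "Maternity"))
  expect_identical(lab2$label[lab2$cluster == 2], "Maternity")
  expect_identical(lab2$source[lab2$cluster == 2], "user")

  # no matching rule -> fallback containing the cluster id
  empty_rules <- default_naming_rules()[0, ]
  lab3 <- suggest_label(dev, naming_rules = empty_rules)
  expect_true(all(grepl("^Cluster [0-9]+:", lab3$label)))
})

test_that("heat-map table mirrors profiles and stays within [0, 100]", {
  coh <- generate_cohort(fixture_cohort_spec(n_patients = 300, seed = 18),
                         make_claims = FALSE)
  pr <- profile_clusters(coh$patient_years, coh$true_labels)
  tab <- export_heatmap_table(pr)
  expect_identical(nrow(tab), 12L)
  expect_identical(ncol(tab), 7L)  # category + 6 clusters
  vals <- as.matrix(tab[, -1])
  expect_true(all(vals >= 0 & vals <= 100))
  for (cl in 1:6) {
    expect_equal(unname(vals[match("PREG", tab$category), cl]),
                 pr$clusters$prev_PREG[pr$clusters$cluster == cl])
  }
  # single cluster: one column equal to cohort prevalences
  pr1 <- profile_clusters(coh$patient_years, rep(1L, nrow(coh$patient_years)))
  tab1 <- export_heatmap_table(pr1)
  expect_equal(unname(as.matrix(tab1[, -1])[, 1]),
               unname(unlist(pr1$grand[paste0("prev_", tab1$category)])))
})

test_that("empty clusters are flagged rather than fatal", {
  py <- hand_cohort()
  pr <- profile_clusters(py, c(1L, 1L, 1L, 1L, 3L, 3L))  # label 2 unused
  expect_setequal(pr$clusters$cluster, c(1L, 3L))
})
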