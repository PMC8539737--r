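# Shared fixtures, built in code at test time.

# A tiny hand-specified two-cluster spec for fast unit tests.
tiny_spec <- function(n = 60, seed = 1, separation = 1) {
  P <- rbind(c(0.9, 0.1, 0.2), c(0.1, 0.9, 0.2))
  colnames(P) <- c("PREG", "CARDIO", "RESP")
  cohort_spec(
    n_patients = n,
    mixing_weights = c(0.5, 0.5),
    condition_prevalence = P,
    demographics = tibble::tibble(age_mean = c(30, 55), age_sd = c(5, 8),
                                  p_female = c(0.9, 0.4)),
    eligibility_prob = matrix(rep(c(0.6, 0.3, 0.07, 0.03), each = 2), nrow = 2,
                              dimnames = list(NULL, c("TANF", "SSI", "Expansion",
                                                      "Medicare-eligible"))),
    race_prob = matrix(rep(c(0.5, 0.2, 0.1, 0.05, 0.02, 0.13), each = 2),
                       nrow = 2,
                       dimnames = list(NULL, c("White", "Black", "Hispanic",
                                               "Asian", "Other", "Missing"))),
    utilization = tibble::tibble(adm_mean = c(0.4, 1.0), adm_sd = c(1.2, 2.0),
                                 days_mean = c(2, 5), ed_mean = c(3, 6),
                                 ed_sd = c(5, 9), p_prev_adm = c(0.1, 0.2),
                                 p_prev_ed = c(0.3, 0.4)),
    separation = separation,
    seed = seed
  )
}

# Hand-built patient-year tibble with explicit values for profiling tests.
hand_cohort <- function() {
  tibble::tibble(
    patient_id = paste0("H", 1:6),
    age = c(30L, 40L, 50L, 20L, 60L, 40L),
    female = c(1L, 1L, 0L, 1L, 0L, 0L),
    eligibility = c("TANF", "TANF", "SSI", "Expansion", "SSI", "TANF"),
    race_ethnicity = c("White", "Black", "White", "Hispanic", "Missing", "White"),
    cond_PREG = c(1L, 1L, 0L, 1L, 0L, 0L),
    cond_CARDIO = c(0L, 0L, 1L, 0L, 1L, 1L),
    admissions = c(0L, 1L, 2L, 0L, 3L, 1L),
    hospital_days = c(0L, 2L, 6L, 0L, 10L, 3L),
    ed_visits = c(2L, 4L, 1L, 3L, 0L, 2L),
    preventable_admissions = c(0L, 1L, 1L, 0L, 2L, 0L),
    preventable_ed_visits = c(1L, 2L, 0L, 1L, 0L, 1L),
    annual_spend = c(1000, 5000, 9000, 1500, 20000, 4000)
  )
}

# Brute-force maximum-total-kappa permutation search (oracle for match_labels).
brute_force_match <- function(K) {
  k <- nrow(K)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- -Inf
  best_p <- NULL
  for (p in perms(seq_len(k))) {
    s <- sum(K[cbind(seq_len(k), p)])
    if (s > best + 1e-12) {
      best <- s
      best_p <- p
    }
  }
  list(total = best, match_of_row = best_p)
}

# Independent 2x2-table kappa (oracle for cohen_kappa).
kappa_oracle <- function(a, b) {
  tab <- table(factor(a, levels = 0:1), factor(b, levels = 0:1))
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- (sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])) / n^2
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# Exhaustive per-patient enumeration oracles for the per-cluster indices.
rand_oracle <- function(orig, repl, universe) {
  agree <- 0
  for (u in universe) {
    agree <- agree + as.integer((u %in% orig) == (u %in% repl))
  }
  100 * agree / length(universe)
}

jaccard_oracle <- function(orig, repl) {
  both <- 0; either <- 0
  for (u in union(orig, repl)) {
    in_o <- u %in% orig; in_r <- u %in% repl
    if (in_o && in_r) both <- both + 1
    if (in_o || in_r) either <- either + 1
  }
  if (either == 0) return(100)
  100 * both / either
}

# Gaussian blob matrix helper for clustering tests.
make_blobs <- function(centers, n_per, sd = 0.1, seed = 1) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_per * ncol(centers), mean = 0, sd = sd),
             ncol = ncol(centers)) +
        matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
    }))
  })
}

# Best-permutation label agreement (oracle for planted-label recovery).
best_permutation_accuracy <- function(assign, truth, k) {
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(k))) {
    best <- max(best, mean(p[assign] == truth))
  }
  best
}
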