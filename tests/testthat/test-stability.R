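test_that("cohen_kappa matches hand computation and the tabulation oracle", {
  expect_equal(cohen_kappa(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  expect_equal(cohen_kappa(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0)
  expect_equal(cohen_kappa(rep(1, 5), rep(1, 5)), 1)  # degenerate equal
  expect_equal(cohen_kappa(rep(1, 5), rep(0, 5)), 0)  # degenerate opposite
  expect_error(cohen_kappa(c(1, 0), c(1, 0, 1)), "equal length")

  withr::with_seed(12, {
    for (i in 1:200) {
      a <- rbinom(200, 1, runif(1, 0.1, 0.9))
      b <- rbinom(200, 1, runif(1, 0.1, 0.9))
      expect_equal(cohen_kappa(a, b), kappa_oracle(a, b), tolerance = 1e-12)
    }
  })
})

test_that("label matching inverts pure permutations with total kappa k", {
  withr::with_seed(3, {
    for (k in c(2, 4, 6)) {
      orig <- sample.int(k, 300, replace = TRUE)
      shift <- ((orig %% k)) + 1L  # cyclic shift
      map <- match_labels(orig, shift, k)
      expect_identical(map$map[shift], orig)
      expect_equal(map$total_kappa, k)
    }
  })
})

test_that("label matching equals brute-force permutation search", {
  withr::with_seed(5, {
    for (i in 1:60) {
      k <- sample(2:5, 1)
      n <- 60
      orig <- sample.int(k, n, replace = TRUE)
      repl <- sample.int(k, n, replace = TRUE)
      map <- match_labels(orig, repl, k)
      oracle <- brute_force_match(map$kappa_matrix)
      expect_equal(map$total_kappa, oracle$total, tolerance = 1e-12)
    }
  })
})

test_that("independent random labels yield near-zero total kappa", {
  withr::with_seed(5, {
    orig <- sample.int(3, 500, replace = TRUE)
    repl <- sample.int(3, 500, replace = TRUE)
    map <- match_labels(orig, repl, 3)
    expect_lt(abs(map$total_kappa), 0.5)
    expect_setequal(map$map, 1:3)  # still a bijection
  })
})

test_that("rand agreement and jaccard overlap follow their definitions", {
  u <- letters[1:4]
  expect_equal(rand_agreement(c("a", "b"), c("a", "b"), u), 100)
  expect_equal(rand_agreement(c("a", "b"), c("a", "c"), u), 50)
  expect_equal(rand_agreement(c("a", "b"), c("c", "d"), u), 0)
  expect_equal(jaccard_overlap(c("a", "b", "c"), c("b", "c", "d")), 50)
  expect_equal(jaccard_overlap(c("a"), c("a")), 100)
  expect_warning(out <- jaccard_overlap(character(0), character(0)), "vacuous")
  expect_equal(out, 100)
  expect_error(rand_agreement("a", "a", character(0)), "non-empty")
})

test_that("indices equal exhaustive enumeration on all small universes", {
  withr::with_seed(8, {
    for (n in 1:8) {
      universe <- paste0("p", seq_len(n))
      for (rep in 1:20) {
        orig_lab <- sample.int(3, n, replace = TRUE)
        repl_lab <- sample.int(3, n, replace = TRUE)
        for (cl in 1:3) {
          om <- universe[orig_lab == cl]
          rm_ <- universe[repl_lab == cl]
          expect_equal(rand_agreement(om, rm_, universe),
                       rand_oracle(om, rm_, universe), tolerance = 1e-12)
          if (length(om) + length(rm_) > 0) {
            expect_equal(jaccard_overlap(om, rm_),
                         jaccard_oracle(om, rm_), tolerance = 1e-12)
          }
        }
      }
    }
  })
})

test_that("perfectly separated point-mass clusters are perfectly stable", {
  x <- rbind(matrix(0, 30, 2), matrix(10, 30, 2), matrix(c(0, 20), 30, 2,
                                                         byrow = TRUE))
  m <- fit_kmeans(x, 3, seed = 1, n_restarts = 3)
  st <- run_stability(x, m, n_replicates = 20, seed = 2, n_restarts = 3)
  expect_true(all(st$per_cluster$jaccard_mean == 100))
  expect_true(all(st$per_cluster$jaccard_sd == 0))
  expect_true(all(st$per_cluster$rand_mean == 100))
  expect_identical(st$n_skipped, 0L)
})

test_that("jaccard never exceeds rand agreement in any replicate", {
  coh <- generate_cohort(stability_demo_spec(n_patients = 300, seed = 3),
                         make_claims = FALSE)
  f <- polar_encode(coh$patient_years)
  m <- fit_kmeans(f, 4, seed = 3, n_restarts = 4)
  st <- run_stability(f, m, n_replicates = 25, seed = 3, n_restarts = 3)
  expect_true(all(st$replicates$jaccard <= st$replicates$rand + 1e-9))
  expect_true(all(st$replicates$rand >= 0 & st$replicates$rand <= 100))
  expect_true(all(st$replicates$jaccard >= 0 & st$replicates$jaccard <= 100))
  expect_true(all(st$per_cluster$rand_sd >= 0 & st$per_cluster$jaccard_sd >= 0))
  expect_true(all(st$per_cluster$jaccard_mean <= st$per_cluster$rand_mean + 1e-9))
})

test_that("a single blob forced into k = 3 is less stable than separated blobs", {
  blob <- make_blobs(matrix(0, 1, 2), 120, sd = 1, seed = 6)
  m_blob <- fit_kmeans(blob, 3, seed = 1, n_restarts = 5)
  st_blob <- run_stability(blob, m_blob, n_replicates = 30, seed = 4,
                           n_restarts = 3)
  sep <- make_blobs(rbind(c(0, 0), c(8, 0), c(0, 8)), 40, sd = 0.3, seed = 6)
  m_sep <- fit_kmeans(sep, 3, seed = 1, n_restarts = 5)
  st_sep <- run_stability(sep, m_sep, n_replicates = 30, seed = 4,
                          n_restarts = 3)
  expect_lt(mean(st_blob$per_cluster$jaccard_mean), 90)
  expect_gt(min(st_sep$per_cluster$jaccard_mean),
            max(st_blob$per_cluster$jaccard_mean))
})

test_that("permuting the reference labels permutes the report rows identically", {
  coh <- generate_cohort(stability_demo_spec(n_patients = 200, seed = 7),
                         make_claims = FALSE)
  f <- polar_encode(coh$patient_years)
  m <- fit_kmeans(f, 3, seed = 2, n_restarts = 4)
  st1 <- run_stability(f, m, n_replicates = 10, seed = 5, n_restarts = 3)
  perm <- c(3L, 1L, 2L)
  m2 <- m
  m2$assignments <- perm[m$assignments]
  m2$centroids <- m$centroids[order(perm), ]
  st2 <- run_stability(f, m2, n_replicates = 10, seed = 5, n_restarts = 3)
  for (cl in 1:3) {
    expect_equal(
      st2$per_cluster[st2$per_cluster$cluster == perm[cl], -1],
      st1$per_cluster[st1$per_cluster$cluster == cl, -1],
      tolerance = 1e-9
    )
  }
})
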