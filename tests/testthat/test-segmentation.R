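test_that("k = 1 recovers the column mean and total sum of squares", {
  x <- make_blobs(rbind(c(0, 0), c(4, 4)), 25, sd = 1, seed = 2)
  m <- fit_kmeans(x, 1, seed = 1, n_restarts = 2)
  expect_equal(as.numeric(m$centroids), colMeans(x), tolerance = 1e-10)
  expect_equal(m$within_sse, sum(scale(x, scale = FALSE)^2), tolerance = 1e-8)
})

test_that("two point-masses are perfectly separated at k = 2", {
  x <- rbind(matrix(0, 50, 2), matrix(10, 50, 2))
  m <- fit_kmeans(x, 2, seed = 1, n_restarts = 3)
  expect_equal(m$within_sse, 0)
  expect_equal(sort(m$centroids[, 1]), c(0, 10))
  expect_identical(length(unique(m$assignments[1:50])), 1L)
  expect_identical(length(unique(m$assignments[51:100])), 1L)
})

test_that("well-separated Gaussians are recovered up to label permutation", {
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5))
  x <- make_blobs(centers, 20, sd = 0.1, seed = 4)
  truth <- rep(1:3, each = 20)
  m <- fit_kmeans(x, 3, seed = 1, n_restarts = 10)
  expect_equal(best_permutation_accuracy(m$assignments, truth, 3), 1)
})

test_that("centroids equal assigned-row means and SSE traces are monotone", {
  coh <- generate_cohort(fixture_cohort_spec(n_patients = 400, seed = 6),
                         make_claims = FALSE)
  f <- polar_encode(coh$patient_years)
  for (k in c(2, 5)) {
    m <- fit_kmeans(f, k, seed = 3, n_restarts = 4)
    for (cl in seq_len(k)) {
      expect_equal(m$centroids[cl, ],
                   colMeans(f$values[m$assignments == cl, , drop = FALSE]),
                   tolerance = 1e-8)
    }
    expect_true(all(diff(m$sse_trace) <= 1e-8))
  }
})

test_that("fit agrees with an independent Lloyd implementation", {
  # same data, both algorithms run to convergence with many restarts:
  # they should reach the same optimum on well-behaved data
  x <- make_blobs(rbind(c(0, 0), c(6, 0), c(0, 6), c(6, 6)), 30,
                  sd = 0.3, seed = 9)
  m <- fit_kmeans(x, 4, seed = 2, n_restarts = 10)
  km <- withr::with_seed(2, stats::kmeans(x, 4, nstart = 10,
                                          algorithm = "Lloyd", iter.max = 100))
  expect_equal(m$within_sse, km$tot.withinss, tolerance = 1e-6)
})

test_that("relabeling input rows permutes assignments identically", {
  x <- make_blobs(rbind(c(0, 0), c(5, 5)), 20, sd = 0.5, seed = 5)
  perm <- withr::with_seed(1, sample(nrow(x)))
  start <- rep(1:2, 20)
  m1 <- fit_kmeans(x, 2, init_assignment = start)
  m2 <- fit_kmeans(x[perm, ], 2, init_assignment = start[perm])
  expect_identical(m2$assignments, m1$assignments[perm])
})

test_that("errors: k > n and non-finite features", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(fit_kmeans(x, 6), "exceeds")
  x[1, 1] <- NA
  expect_error(fit_kmeans(x, 2), "non-finite")
})

test_that("partial F follows its closed form", {
  expect_equal(partial_f(200, 100, 102, 1, 1), 100)
  expect_equal(partial_f(50, 50, 100, 2, 3), 0)
  expect_identical(partial_f(10, 0, 100, 2, 3), Inf)
  expect_error(partial_f(10, 20, 100, 2, 3), "sse_k")
  expect_error(partial_f(10, 5, 8, 2, 3), "exceed")
  # a constructed SSE sequence with one sharp drop peaks at the drop
  sse <- c(100, 90, 80, 20, 19, 18.5)
  f <- sapply(1:5, function(k) partial_f(sse[k], sse[k + 1], 500, k, 2))
  expect_identical(which.max(f), 3L)  # the k=3 -> 4 transition
})

test_that("select_k finds planted structure and handles boundary grids", {
  # 2 well-separated blobs
  x <- make_blobs(rbind(c(0, 0), c(8, 8)), 100, sd = 0.5, seed = 3)
  ks <- select_k(x, 2:10, seed = 3, n_restarts = 5)
  expect_identical(ks$selected_k, 2L)
  expect_true(all(diff(ks$curve$sse) <= 1e-8))

  # boundary grid {2, 3}: one transition only, selection stays in-grid
  xs <- make_blobs(rbind(c(0, 0), c(4, 4)), 5, sd = 0.5, seed = 8)
  ks2 <- select_k(xs, 2:3, seed = 1, n_restarts = 3)
  expect_identical(sum(!is.na(ks2$curve$partial_f[ks2$curve$k >= 2])), 1L)
  expect_true(ks2$selected_k %in% 2:3)

  expect_error(select_k(x, c(2, 4)), "contiguous")
  expect_error(select_k(x, integer(0)), "empty")
})

test_that("select_k recovers six planted clusters on the fixture", {
  coh <- generate_cohort(fixture_cohort_spec(n_patients = 3000,
                                             separation = 3, seed = 11),
                         make_claims = FALSE)
  f <- polar_encode(coh$patient_years)
  ks <- select_k(f, 2:12, seed = 11, n_restarts = 8)
  expect_identical(ks$selected_k, 6L)
})

test_that("best-of-restarts SSE is non-increasing in the restart budget", {
  coh <- generate_cohort(fixture_cohort_spec(n_patients = 300, seed = 2),
                         make_claims = FALSE)
  f <- polar_encode(coh$patient_years)
  sse <- sapply(c(1, 3, 6), function(r) {
    fit_kmeans(f, 5, seed = 4, n_restarts = r)$within_sse
  })
  expect_true(all(diff(sse) <= 1e-10))
})
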