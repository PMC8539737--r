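#' Fit k-means by Lloyd's algorithm with restarts
#'
#' Partitional clustering: every observation is assigned to exactly one of
#' `k` non-overlapping clusters. Each restart begins from a random
#' partition (every observation assigned to a cluster at random, the
#' classical description of the algorithm), then alternates assignment to
#' the nearest centroid with centroid recomputation until assignments are
#' stable or the relative SSE change falls below `tol`. The within-cluster
#' sum of squared errors is non-increasing across iterations; the trace is
#' kept on the fitted object. A cluster left empty after reassignment is
#' repaired by reseeding its centroid at the observation farthest from its
#' current centroid. The best (lowest-SSE) restart is returned.
#'
#' @param features An `hcn_features` object or numeric matrix.
#' @param k Number of clusters (1 <= k <= n).
#' @param seed Integer seed; restart r uses seed + r - 1.
#' @param n_restarts Number of random restarts (default 10).
#' @param max_iter Maximum Lloyd iterations per restart (default 300).
#' @param tol Relative SSE convergence tolerance (default 1e-6).
#' @param init `"random-partition"` (default) or `"kmeans++"`.
#' @param init_centroids Optional k x p matrix of starting centroids; when
#'   given it is used as one additional deterministic restart.
#' @param init_assignment Optional explicit starting partition (single
#'   deterministic run; used for invariance checks).
#' @return An object of class `hcn_kmeans`: `k`, `centroids`,
#'   `assignments`, `within_sse`, `n_iter`, `sse_trace`, `seed`,
#'   `row_ids`.
#' @export
fit_kmeans <- function(features, k, seed = 1, n_restarts = 10,
                       max_iter = 300, tol = 1e-6,
                       init = c("random-partition", "kmeans++"),
                       init_centroids = NULL, init_assignment = NULL) {
  init <- match.arg(init)
  x <- feature_values(features)
  n <- nrow(x)
  if (!is_count(k) || k < 1) abort("`k` must be a positive integer.")
  if (k > n) abort(sprintf("k = %d exceeds the number of observations (%d).", k, n))
  if (!all(is.finite(x))) abort("features contain non-finite values.")

  runs <- list()
  if (!is.null(init_assignment)) {
    if (length(init_assignment) != n) abort("`init_assignment` must have one entry per observation.")
    runs <- list(lloyd(x, k, start_assignment = as.integer(init_assignment),
                       max_iter = max_iter, tol = tol))
  } else {
    for (r in seq_len(n_restarts)) {
      runs[[r]] <- with_seed(derive_seed(seed, r - 1), {
        start <- if (init == "kmeans++") NULL else random_partition(n, k)
        cen <- if (init == "kmeans++") kmeanspp_centroids(x, k) else NULL
        lloyd(x, k, start_assignment = start, start_centroids = cen,
              max_iter = max_iter, tol = tol)
      })
    }
    if (!is.null(init_centroids)) {
      runs[[length(runs) + 1]] <- with_seed(derive_seed(seed, n_restarts), {
        lloyd(x, k, start_centroids = init_centroids,
              max_iter = max_iter, tol = tol)
      })
    }
  }
  best <- runs[[which.min(vapply(runs, function(r) r$within_sse, numeric(1)))]]
  structure(
    list(k = as.integer(k), centroids = best$centroids,
         assignments = best$assignments, within_sse = best$within_sse,
         n_iter = best$n_iter, sse_trace = best$sse_trace,
         seed = seed, row_ids = feature_row_ids(features)),
    class = "hcn_kmeans"
  )
}

#' @export
print.hcn_kmeans <- function(x, ...) {
  cat("<hcn_kmeans> k =", x$k, " n =", length(x$assignments),
      " within-SSE =", format(x$within_sse, digits = 6),
      " (", x$n_iter, "iterations )\n")
  cat("cluster sizes:", paste(tabulate(x$assignments, x$k), collapse = ", "), "\n")
  invisible(x)
}

# Random partition with every cluster non-empty (n >= k).
random_partition <- function(n, k) {
  base <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  sample(base, n)
}

kmeanspp_centroids <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx[1], ], "-")^2)
  for (j in seq_len(k - 1) + 1) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[idx[j], ], "-")^2))
  }
  x[idx, , drop = FALSE]
}

# One Lloyd run. Starts either from an assignment (centroids computed from
# it) or from explicit centroids (assignment step first).
lloyd <- function(x, k, start_assignment = NULL, start_centroids = NULL,
                  max_iter = 300, tol = 1e-6) {
  n <- nrow(x)
  if (!is.null(start_assignment)) {
    assignment <- start_assignment
    centroids <- centroid_means(x, assignment, k)
  } else {
    centroids <- as.matrix(start_centroids)
    assignment <- max.col(-rowdist2(x, centroids), ties.method = "first")
    centroids <- centroid_means(x, assignment, k, fallback = centroids)
  }
  sse_trace <- numeric(0)
  sse <- Inf
  for (iter in seq_len(max_iter)) {
    d2 <- rowdist2(x, centroids)
    new_assignment <- max.col(-d2, ties.method = "first")

    # empty-cluster repair: reseed at the observation farthest from its centroid
    empty <- setdiff(seq_len(k), unique(new_assignment))
    while (length(empty) > 0) {
      cur <- d2[cbind(seq_len(n), new_assignment)]
      far <- which.max(cur)
      centroids[empty[1], ] <- x[far, ]
      new_assignment[far] <- empty[1]
      d2[, empty[1]] <- rowSums(sweep(x, 2, centroids[empty[1], ], "-")^2)
      empty <- setdiff(seq_len(k), unique(new_assignment))
    }

    new_sse <- sum(d2[cbind(seq_len(n), new_assignment)])
    sse_trace <- c(sse_trace, new_sse)
    stable <- identical(new_assignment, if (iter > 1) assignment else NULL)
    converged <- is.finite(sse) && (sse - new_sse) <= tol * max(sse, 1e-300)
    assignment <- new_assignment
    centroids <- centroid_means(x, assignment, k, fallback = centroids)
    sse <- new_sse
    if (stable || converged) break
  }
  # report the SSE about the final centroids (means of assigned rows)
  final_sse <- sum(rowdist2(x, centroids)[cbind(seq_len(n), assignment)])
  list(centroids = centroids, assignments = assignment,
       within_sse = final_sse, n_iter = length(sse_trace),
       sse_trace = sse_trace)
}

centroid_means <- function(x, assignment, k, fallback = NULL) {
  counts <- tabulate(assignment, k)
  cen <- matrix(0, nrow = k, ncol = ncol(x),
                dimnames = list(NULL, colnames(x)))
  sums <- rowsum(x, group = factor(assignment, levels = seq_len(k)))
  nonzero <- counts > 0
  cen[nonzero, ] <- sums[nonzero, , drop = FALSE] / counts[nonzero]
  if (any(!nonzero)) {
    if (is.null(fallback)) {
      cen[!nonzero, ] <- x[sample.int(nrow(x), sum(!nonzero)), , drop = FALSE]
    } else {
      cen[!nonzero, ] <- fallback[!nonzero, , drop = FALSE]
    }
  }
  cen
}

#' Partial F statistic for the k -> k+1 transition
#'
#' Mean-square improvement from adding one cluster over the residual
#' mean-square of the (k+1)-cluster solution, with `p` coordinates per
#' centroid:
#' `((sse_k - sse_k_plus_1) / p) / (sse_k_plus_1 / (n - (k + 1) * p))`.
#' Returns `Inf` when the (k+1)-cluster solution has zero error.
#'
#' @param sse_k,sse_k_plus_1 Within-cluster SSE at k and k+1 clusters;
#'   `sse_k >= sse_k_plus_1 >= 0`.
#' @param n Number of observations.
#' @param k Number of clusters before the transition.
#' @param p Number of feature coordinates.
#' @return A non-negative scalar (possibly `Inf`).
#' @export
partial_f <- function(sse_k, sse_k_plus_1, n, k, p) {
  if (sse_k_plus_1 < 0 || sse_k < sse_k_plus_1) {
    abort("need sse_k >= sse_k_plus_1 >= 0.")
  }
  df2 <- n - (k + 1) * p
  if (df2 <= 0) abort("n must exceed (k + 1) * p for the partial F statistic.")
  if (sse_k_plus_1 == 0) return(Inf)
  ((sse_k - sse_k_plus_1) / p) / (sse_k_plus_1 / df2)
}

#' Select the number of clusters by the jump in the partial F curve
#'
#' Fits k-means over a contiguous grid of k (default 2..20, plus k = 1
#' internally so the first grid point has a preceding transition), computes
#' the partial F statistic of every k -> k+1 transition, and selects the k
#' whose incoming transition shows the largest jump: operationally, the k
#' after which the partial F curve drops the most, proportionally, between
#' successive transitions (the elbow of the curve). The improvement
#' statistic stays high while transitions still split real structure and
#' collapses once they start splitting noise, so the largest proportional
#' (log-scale) drop marks the true k; a proportional rather than absolute
#' drop is used because the statistic's overall magnitude shrinks with k,
#' which would otherwise bias the rule toward small k. A Sugar-James style
#' transformed distortion criterion is available as an alternative.
#'
#' Monotonicity of SSE in k is enforced by warm-starting each k with the
#' previous best solution augmented by one centroid at the farthest
#' observation, in addition to the random restarts.
#'
#' @param features An `hcn_features` object or numeric matrix.
#' @param k_grid Contiguous increasing integer grid (default 2:20).
#' @param seed Integer seed.
#' @param n_restarts Restarts per k (default 10).
#' @param criterion `"partial_f_jump"` (default) or `"distortion_jump"`.
#' @param ... Passed to [fit_kmeans()] (`max_iter`, `tol`, `init`).
#' @return An object of class `hcn_kcurve`: tibble `curve` (k, sse,
#'   partial_f for the k -> k+1 transition), `selected_k`, `criterion`,
#'   `models` (fitted `hcn_kmeans` per k), `seed`.
#' @export
select_k <- function(features, k_grid = 2:20, seed = 1, n_restarts = 10,
                     criterion = c("partial_f_jump", "distortion_jump"), ...) {
  criterion <- match.arg(criterion)
  x <- feature_values(features)
  n <- nrow(x)
  p <- ncol(x)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 0) abort("`k_grid` is empty.")
  if (min(k_grid) < 2 || max(k_grid) > n - 1) {
    abort("`k_grid` must lie within [2, n - 1].")
  }
  if (length(k_grid) > 1 && any(diff(k_grid) != 1)) {
    abort("`k_grid` must be contiguous (step 1) for transition statistics.")
  }

  ks <- c(1L, k_grid)
  sse <- numeric(length(ks))
  models <- vector("list", length(ks))
  prev <- NULL
  for (i in seq_along(ks)) {
    k <- ks[i]
    warm <- NULL
    if (!is.null(prev)) {
      far <- which.max(rowdist2(x, prev$centroids)[cbind(seq_len(n),
                                                         prev$assignments)])
      warm <- rbind(prev$centroids, x[far, ])
    }
    fit <- tryCatch(
      fit_kmeans(features, k, seed = derive_seed(seed, 1000 * k),
                 n_restarts = n_restarts, init_centroids = warm, ...),
      error = function(e) abort(sprintf("k-means failed at k = %d: %s", k,
                                        conditionMessage(e)))
    )
    sse[i] <- fit$within_sse
    # the warm start guarantees improvement up to FP noise; clamp the rest
    if (i > 1 && sse[i] > sse[i - 1]) sse[i] <- sse[i - 1]
    models[[i]] <- fit
    prev <- fit
  }

  # transition statistics: pf[i] is the partial F of ks[i] -> ks[i] + 1
  m <- length(ks)
  pf <- rep(NA_real_, m)
  for (i in seq_len(m - 1)) {
    pf[i] <- partial_f(sse[i], sse[i + 1], n, ks[i], p)
  }

  if (criterion == "partial_f_jump") {
    if (any(is.infinite(pf) & pf > 0)) {
      # zero residual: the first transition reaching SSE 0 marks the elbow
      selected_k <- ks[which(is.infinite(pf))[1]] + 1L
    } else if (m >= 3) {
      # proportional drop between successive transitions: the statistic
      # falls off hardest right after the transition into the true k.
      # The curve is first clamped to its non-increasing envelope (the
      # statistic is a monotonically decreasing one; local bumps are
      # noise) and floored at F = 1, the no-improvement baseline of a
      # mean-square ratio, so fluctuations below baseline cannot fake a
      # jump.
      pf_mono <- pmax(cummin(pf[seq_len(m - 1)]), 1)
      lpf <- log(pf_mono)
      drops <- lpf[seq_len(m - 2)] - lpf[seq_len(m - 2) + 1]
      drops[!is.finite(drops)] <- -Inf
      selected_k <- ks[which.max(drops) + 1L]
    } else {
      # a single transition: no drop to compare, take its target k
      selected_k <- ks[m]
    }
  } else {
    d <- sse / (n * p)
    jump <- d[-1]^(-p / 2) - d[-m]^(-p / 2)
    selected_k <- ks[-1][which.max(jump)]
  }

  curve <- tibble::tibble(k = ks, sse = sse, partial_f = pf)
  structure(list(curve = curve, selected_k = as.integer(selected_k),
                 criterion = criterion,
                 models = setNames(models, paste0("k", ks)), seed = seed),
            class = "hcn_kcurve")
}

#' @export
print.hcn_kcurve <- function(x, ...) {
  cat("<hcn_kcurve> criterion:", x$criterion,
      " grid:", min(x$curve$k[-1]), "-", max(x$curve$k),
      " selected k =", x$selected_k, "\n")
  invisible(x)
}
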