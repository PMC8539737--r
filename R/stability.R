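#' Cohen's kappa for two binary vectors
#'
#' Chance-corrected agreement from the 2x2 table of `a` vs `b`:
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o` and expected
#' agreement `p_e` from the marginals. When both vectors are constant the
#' table is degenerate: kappa is defined as 1 when they are identical
#' (perfect, if vacuous, agreement) and 0 otherwise.
#'
#' @param a,b Equal-length binary (0/1 or logical) vectors.
#' @return A scalar in \[-1, 1\].
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  if (length(a) == 0) abort("`a` and `b` must have length >= 1.")
  a <- as.integer(as.logical(a))
  b <- as.integer(as.logical(b))
  po <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  pe <- pa * pb + (1 - pa) * (1 - pb)
  if (pe >= 1) return(if (po >= 1) 1 else 0)
  (po - pe) / (1 - pe)
}

# Hungarian algorithm (shortest augmenting path with potentials) for the
# square linear assignment problem, minimising sum cost[i, match[i]].
# O(k^3); exact. Columns are 1..n with a virtual column 0 (index offset +1).
hungarian_min <- function(cost) {
  n <- nrow(cost)
  if (ncol(cost) != n) abort("cost matrix must be square.")
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j]) { minv[j] <- cur; way[j + 1] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  match_of_row <- integer(n)
  for (j in seq_len(n)) match_of_row[p[j + 1]] <- j
  match_of_row
}

#' Match bootstrap cluster labels to the original labels by kappa
#'
#' Cluster numbering after a refit is arbitrary, so replicate labels are
#' re-mapped onto the original labels before stability indices are
#' computed. The map is the one-to-one label permutation maximising the
#' total Cohen's kappa between original and relabeled per-cluster
#' membership indicators, found by optimal assignment on the k x k kappa
#' matrix (not greedily), which is deterministic and order-independent.
#'
#' @param original,replicate Integer cluster assignments over the same
#'   patients, using labels in 1..k.
#' @param k Number of clusters.
#' @return An object of class `hcn_label_map`: integer vector `map` such
#'   that `map[replicate]` is on the original labeling, plus `total_kappa`
#'   and the `kappa_matrix`.
#' @export
match_labels <- function(original, replicate, k) {
  if (length(original) != length(replicate)) {
    abort("`original` and `replicate` must cover the same patients.")
  }
  if (max(original, 0) > k || max(replicate, 0) > k) {
    abort("assignments use labels above `k`.")
  }
  K <- matrix(0, k, k)
  for (i in seq_len(k)) {
    oi <- original == i
    for (j in seq_len(k)) {
      K[i, j] <- cohen_kappa(oi, replicate == j)
    }
  }
  match_of_row <- hungarian_min(-K)  # maximise total kappa
  map <- integer(k)
  map[match_of_row] <- seq_len(k)    # map[replicate label] = original label
  structure(list(map = map,
                 total_kappa = sum(K[cbind(seq_len(k), match_of_row)]),
                 kappa_matrix = K),
            class = "hcn_label_map")
}

#' Per-cluster binary-membership agreement (Rand-style) and overlap (Jaccard)
#'
#' Both indices compare one cluster's membership between the original
#' partition and a (relabeled) replicate partition over a common patient
#' universe. `rand_agreement()` is the percentage of patients on which the
#' two partitions agree about membership in the cluster (in it in both, or
#' out of it in both). `jaccard_overlap()` counts only joint members as a
#' percentage of patients placed in the cluster by either partition — a
#' stricter measure; algebraically Jaccard <= Rand agreement always. Both
#' are per-cluster binary-membership indices, not the pair-counting global
#' Rand index over whole partitions.
#'
#' @param original_members,replicate_members Patient-id vectors (members of
#'   the cluster under each partition).
#' @param universe Patient-id vector of the common comparison population.
#' @return A percentage in \[0, 100\].
#' @export
rand_agreement <- function(original_members, replicate_members, universe) {
  if (length(universe) == 0) abort("`universe` must be non-empty.")
  in_o <- universe %in% original_members
  in_r <- universe %in% replicate_members
  100 * sum(in_o == in_r) / length(universe)
}

#' @rdname rand_agreement
#' @export
jaccard_overlap <- function(original_members, replicate_members) {
  i <- length(intersect(original_members, replicate_members))
  u <- length(union(original_members, replicate_members))
  if (u == 0) {
    warn("both membership sets empty; Jaccard overlap defined as 100 (vacuous agreement).")
    return(100)
  }
  100 * i / u
}

#' Bootstrap cluster-stability assessment
#'
#' Quantifies how reliably patients land in the same cluster under
#' resampling. For each replicate the cohort is resampled with replacement
#' (size n), k-means is refit with the same k (seed derived from the master
#' seed by replicate index), replicate labels are matched to the original
#' labels by [match_labels()], and per-cluster [rand_agreement()] and
#' [jaccard_overlap()] are computed over the comparison population —
#' by default the unique patients present in the bootstrap sample
#' (duplicates collapsed, each patient contributing one membership
#' comparison), optionally the full original cohort with out-of-sample
#' patients assigned to the nearest replicate centroid. Replicates whose
#' refit fails are skipped and counted, never silently absorbed.
#'
#' @param features The `hcn_features` (or matrix) the reference model was
#'   fitted on.
#' @param reference An `hcn_kmeans` fitted on `features`.
#' @param n_replicates Number of bootstrap replicates (default 500).
#' @param seed Master seed; replicate r uses seed + r.
#' @param n_restarts Restarts per refit (default 10).
#' @param comparison `"unique"` (default) or `"full"`.
#' @param ... Passed to [fit_kmeans()].
#' @return An object of class `hcn_stability`: `per_cluster` (tibble:
#'   cluster, n_ref, rand_mean, rand_sd, jaccard_mean, jaccard_sd),
#'   `overall` (means of the per-cluster values), `replicates` (tibble:
#'   replicate, cluster, rand, jaccard), `n_replicates`, `n_skipped`,
#'   `seed`.
#' @export
run_stability <- function(features, reference, n_replicates = 500, seed = 1,
                          n_restarts = 10,
                          comparison = c("unique", "full"), ...) {
  comparison <- match.arg(comparison)
  if (!inherits(reference, "hcn_kmeans")) abort("`reference` must be an hcn_kmeans fit.")
  x <- feature_values(features)
  n <- nrow(x)
  if (length(reference$assignments) != n) {
    abort("`reference` was not fitted on these features.")
  }
  k <- reference$k
  ids <- feature_row_ids(features)

  rows <- vector("list", n_replicates)
  n_skipped <- 0L
  for (r in seq_len(n_replicates)) {
    idx <- with_seed(derive_seed(seed, r), sample.int(n, n, replace = TRUE))
    fit <- tryCatch(
      fit_kmeans(x[idx, , drop = FALSE], k, seed = derive_seed(seed, r),
                 n_restarts = n_restarts, ...),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (comparison == "unique") {
      uniq <- unique(idx)
      orig <- reference$assignments[uniq]
      repl <- fit$assignments[match(uniq, idx)]
      universe <- ids[uniq]
      orig_ids <- ids[uniq]
    } else {
      orig <- reference$assignments
      # sampled patients keep their fitted assignment (first occurrence);
      # out-of-sample patients go to the nearest replicate centroid
      repl <- max.col(-rowdist2(x, fit$centroids), ties.method = "first")
      repl[unique(idx)] <- fit$assignments[match(unique(idx), idx)]
      universe <- ids
      orig_ids <- ids
    }
    map <- match_labels(orig, repl, k)
    relabeled <- map$map[repl]
    for (cl in seq_len(k)) {
      om <- orig_ids[orig == cl]
      rm_ <- orig_ids[relabeled == cl]
      jac <- if (length(om) == 0 && length(rm_) == 0) {
        100  # cluster absent from this bootstrap sample on both sides
      } else {
        jaccard_overlap(om, rm_)
      }
      rows[[r]] <- dplyr::bind_rows(
        rows[[r]],
        tibble::tibble(replicate = r, cluster = cl,
                       rand = rand_agreement(om, rm_, universe),
                       jaccard = jac)
      )
    }
  }
  replicates <- dplyr::bind_rows(rows)
  if (nrow(replicates) == 0) abort("all bootstrap replicates failed.")

  per_cluster <- replicates |>
    dplyr::group_by(cluster = .data$cluster) |>
    dplyr::summarise(
      rand_mean = mean(.data$rand),
      rand_sd = stats::sd(.data$rand),
      jaccard_mean = mean(.data$jaccard),
      jaccard_sd = stats::sd(.data$jaccard),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_ref = tabulate(reference$assignments, k)[.data$cluster],
                  .after = "cluster")
  overall <- per_cluster |>
    dplyr::summarise(dplyr::across(c("rand_mean", "rand_sd",
                                     "jaccard_mean", "jaccard_sd"), mean))
  structure(list(per_cluster = per_cluster, overall = overall,
                 replicates = replicates,
                 n_replicates = as.integer(n_replicates),
                 n_skipped = n_skipped, seed = seed),
            class = "hcn_stability")
}

#' @export
print.hcn_stability <- function(x, ...) {
  cat("<hcn_stability>", x$n_replicates, "bootstrap replicates",
      if (x$n_skipped > 0) paste0("(", x$n_skipped, " skipped)") else "", "\n")
  print(x$per_cluster)
  invisible(x)
}
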