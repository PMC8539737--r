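#' Tidy a fitted k-means partition
#'
#' One row per cluster: size, share of the cohort, and the within-cluster
#' sum of squared errors contribution.
#'
#' @param x An `hcn_kmeans` object.
#' @param features Optional features the model was fitted on, to compute
#'   per-cluster SSE; omitted columns are NA without it.
#' @param ... Unused.
#' @return A tibble with columns cluster, size, share_pct, within_sse.
#' @method tidy hcn_kmeans
#' @export
tidy.hcn_kmeans <- function(x, features = NULL, ...) {
  sizes <- tabulate(x$assignments, x$k)
  out <- tibble::tibble(cluster = seq_len(x$k), size = sizes,
                        share_pct = 100 * sizes / length(x$assignments),
                        within_sse = NA_real_)
  if (!is.null(features)) {
    xm <- feature_values(features)
    d2 <- rowdist2(xm, x$centroids)[cbind(seq_len(nrow(xm)), x$assignments)]
    out$within_sse <- as.numeric(rowsum(d2, factor(x$assignments,
                                                   levels = seq_len(x$k))))
  }
  out
}

#' @rdname tidy.hcn_kmeans
#' @method glance hcn_kmeans
#' @export
glance.hcn_kmeans <- function(x, ...) {
  tibble::tibble(k = x$k, n = length(x$assignments),
                 within_sse = x$within_sse, n_iter = x$n_iter,
                 seed = x$seed)
}

#' Tidy a k-selection curve
#'
#' @param x An `hcn_kcurve` object.
#' @param ... Unused.
#' @return The curve tibble (k, sse, partial_f) with a `selected` flag.
#' @method tidy hcn_kcurve
#' @export
tidy.hcn_kcurve <- function(x, ...) {
  dplyr::mutate(x$curve, selected = .data$k == x$selected_k)
}

#' @rdname tidy.hcn_kcurve
#' @method glance hcn_kcurve
#' @export
glance.hcn_kcurve <- function(x, ...) {
  tibble::tibble(selected_k = x$selected_k, criterion = x$criterion,
                 k_min = min(x$curve$k[-1]), k_max = max(x$curve$k),
                 seed = x$seed)
}

#' Tidy a stability report
#'
#' @param x An `hcn_stability` object.
#' @param ... Unused.
#' @return The per-cluster tibble of Rand / Jaccard means and SDs.
#' @method tidy hcn_stability
#' @export
tidy.hcn_stability <- function(x, ...) {
  x$per_cluster
}

#' @rdname tidy.hcn_stability
#' @method glance hcn_stability
#' @export
glance.hcn_stability <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n_replicates = x$n_replicates,
                                  n_skipped = x$n_skipped, seed = x$seed),
                   x$overall)
}

#' Tidy cluster profiles
#'
#' @param x An `hcn_profiles` object.
#' @param ... Unused.
#' @return The per-cluster profile tibble.
#' @method tidy hcn_profiles
#' @export
tidy.hcn_profiles <- function(x, ...) {
  x$clusters
}

#' @rdname tidy.hcn_profiles
#' @method glance hcn_profiles
#' @export
glance.hcn_profiles <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(n = x$n, n_clusters = nrow(x$clusters)),
                   dplyr::select(x$grand, -"cluster", -"share_pct", -"n"))
}
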