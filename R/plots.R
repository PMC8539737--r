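#' Plot the partial F curve for choosing k
#'
#' The improvement statistic of each k -> k+1 transition against k; the
#' selected number of clusters is marked. The elbow — the largest drop
#' between successive transitions — is where adding clusters stops
#' explaining real structure.
#'
#' @param object An `hcn_kcurve` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hcn_kcurve
#' @export
autoplot.hcn_kcurve <- function(object, ...) {
  df <- dplyr::filter(object$curve, is.finite(.data$partial_f))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$partial_f)) +
    ggplot2::geom_line(color = "grey40") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$selected_k, linetype = 2,
                        color = "firebrick") +
    ggplot2::labs(x = "number of clusters k (transition k → k+1)",
                  y = "partial F statistic",
                  title = sprintf("Jump criterion: selected k = %d",
                                  object$selected_k)) +
    ggplot2::theme_minimal()
}

#' Plot per-cluster bootstrap stability
#'
#' Mean Rand agreement and Jaccard overlap per cluster with +/- 1 SD bars.
#'
#' @param object An `hcn_stability` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hcn_stability
#' @export
autoplot.hcn_stability <- function(object, ...) {
  df <- object$per_cluster |>
    tidyr::pivot_longer(c("rand_mean", "jaccard_mean"),
                        names_to = "index", values_to = "mean") |>
    dplyr::mutate(
      sd = ifelse(.data$index == "rand_mean", .data$rand_sd, .data$jaccard_sd),
      index = ifelse(.data$index == "rand_mean", "Rand agreement", "Jaccard overlap")
    )
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster), y = .data$mean,
                                   fill = .data$index)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                   ymax = pmin(.data$mean + .data$sd, 100)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25) +
    ggplot2::labs(x = "cluster", y = "stability index (%)", fill = NULL,
                  title = "Bootstrap cluster stability") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Condition-prevalence heat map by cluster
#'
#' The classic cluster-profile display: condition categories by cluster,
#' tile-shaded by prevalence (%).
#'
#' @param profiles An `hcn_profiles` object.
#' @param category_order Optional category ordering.
#' @return A ggplot.
#' @export
plot_condition_heatmap <- function(profiles, category_order = NULL) {
  tab <- export_heatmap_table(profiles, category_order)
  long <- tidyr::pivot_longer(tab, -"category", names_to = "cluster",
                              values_to = "prevalence") |>
    dplyr::mutate(cluster = sub("^cluster_", "", .data$cluster),
                  category = factor(.data$category, levels = rev(tab$category)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$cluster, y = .data$category,
                                     fill = .data$prevalence)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_gradient(low = "#fff5eb", high = "#7f2704",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "cluster", y = NULL, fill = "prevalence (%)",
                  title = "Condition prevalence by cluster") +
    ggplot2::theme_minimal()
}
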