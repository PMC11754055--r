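#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of an individual similarity network
#'
#' @param object A `morph_similarity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.morph_similarity <- function(object, ...) {
  edges <- tidy(object)
  full <- dplyr::bind_rows(
    edges,
    dplyr::rename(edges, from = "to", to = "from",
                  from_region = "to_region", to_region = "from_region")
  )
  ggplot2::ggplot(full, ggplot2::aes(.data$from, .data$to,
                                     fill = .data$weight)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = object$method) +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("Individual morphological network (%s)",
                      object$subject_id),
      x = "region", y = "region"
    ) +
    ggplot2::theme_minimal()
}

#' Global metric curves across the sparsity sweep
#'
#' @param object A `morph_curves` from [subject_curves()].
#' @param ... Unused.
#' @return A ggplot object, one facet per global metric.
#' @export
autoplot.morph_curves <- function(object, ...) {
  tidy(object, which = "global") |>
    ggplot2::ggplot(ggplot2::aes(.data$threshold, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      title = sprintf("Global network metrics (%s)",
                      object$subject_id %||% ""),
      x = "sparsity threshold", y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Group comparison of metric AUC distributions
#'
#' Boxplots of per-subject AUCs by group, one facet per metric — the visual
#' counterpart of the global AUC group tests.
#'
#' @param global_auc Tibble from [cohort_network_aucs()]`$global` (columns
#'   `subject_id`, `group`, one column per metric).
#' @return A ggplot object.
#' @export
plot_global_auc <- function(global_auc) {
  tidyr::pivot_longer(global_auc, -c("subject_id", "group"),
                      names_to = "metric", values_to = "auc") |>
    ggplot2::ggplot(ggplot2::aes(.data$group, .data$auc,
                                 fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "AUC over sparsity range") +
    ggplot2::theme_minimal()
}

#' Nodal FDR results along the atlas
#'
#' Manhattan-style view of the region-wise group tests: -log10 adjusted p
#' per region, FDR survivors highlighted, one facet per nodal metric.
#'
#' @param nodal_tests Output of [nodal_group_analysis()].
#' @param q The FDR level drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_nodal_tests <- function(nodal_tests, q = 0.05) {
  nodal_tests |>
    dplyr::mutate(node = as.integer(factor(.data$region,
                                           levels = unique(.data$region)))) |>
    ggplot2::ggplot(ggplot2::aes(.data$node, -log10(.data$adjusted_p),
                                 colour = .data$survivor)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(q), linetype = 2) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "atlas region index", y = "-log10 FDR-adjusted p",
                  colour = "survivor") +
    ggplot2::theme_minimal()
}
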