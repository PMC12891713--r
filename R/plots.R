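#' Plot a two-objective projection of a Pareto analysis
#'
#' Scatter of all candidate treatments on two objectives with the
#' non-dominated set highlighted, mirroring the usual yield-quality
#' trade-off view.
#'
#' @param object A [pareto_front()] result.
#' @param axes Two objective names; default the first two objectives.
#' @param label Optional column used to label frontier points.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot pareto_front
#' @export
autoplot.pareto_front <- function(object, axes = NULL, label = "cultivar",
                                  ...) {
  objectives <- attr(object, "objectives")
  if (is.null(axes)) axes <- objectives[1:2]
  d <- frontier_projection(object, axes)
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]])
  ) +
    ggplot2::geom_point(
      ggplot2::aes(colour = .data$.frontier, shape = .data$.frontier),
      size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#1f6fb4", `FALSE` = "grey60"),
      name = "Non-dominated"
    ) +
    ggplot2::scale_shape_manual(
      values = c(`TRUE` = 17, `FALSE` = 16), name = "Non-dominated"
    ) +
    ggplot2::labs(x = axes[1], y = axes[2]) +
    ggplot2::theme_minimal()
  if (!is.null(label) && label %in% names(d)) {
    p <- p + ggplot2::geom_text(
      data = dplyr::filter(d, .data$.frontier),
      ggplot2::aes(label = .data[[label]]),
      vjust = -0.9, size = 3
    )
  }
  p
}

#' Heatmap of the normalized treatment performance matrix
#'
#' Treatments by metrics tile plot on the 0-100 scale (viridis fill: yellow
#' best, dark purple worst).
#'
#' @param object A [performance_matrix()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot melon_performance
#' @export
autoplot.melon_performance <- function(object, ...) {
  metrics <- attr(object, "metrics")
  d <- as_tibble(object) %>%
    mutate(treatment = treatment_key(object)) %>%
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric",
                        values_to = "score")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$treatment,
                                  fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$score)), size = 3) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 100), name = "Score") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Stacked bars of per-treatment grade distributions
#'
#' @param dist Output of [grade_distribution()].
#' @return A ggplot.
#' @export
plot_grade_distribution <- function(dist) {
  d <- mutate(dist, treatment = paste0(.data$substrate_volume, "L/",
                                       .data$plants_per_slab, "p"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$treatment, y = .data$pct,
                                  fill = .data$grade)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~cultivar) +
    ggplot2::scale_fill_manual(values = c(
      Premium = "#1b7837", Superior = "#7fbf7b",
      Medium = "#d9f0a3", Inferior = "#c2a57b"
    )) +
    ggplot2::labs(x = NULL, y = "% of fruits", fill = "Grade") +
    ggplot2::theme_minimal()
}

#' Revenue, cost and net profit per treatment
#'
#' Revenue as positive bars, total cost as negative bars, net profit as a
#' line with points; the zero line is break-even.
#'
#' @param object An [economic_summary()] result.
#' @param ... Ignored.
#' @return A ggplot.
#' @method autoplot melon_economics
#' @export
autoplot.melon_economics <- function(object, ...) {
  d <- mutate(as_tibble(object), treatment = treatment_key(object))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$treatment)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$total_revenue,
                                   fill = .data$cultivar)) +
    ggplot2::geom_col(ggplot2::aes(y = -.data$total_cost),
                      fill = "#c6b3d3") +
    ggplot2::geom_point(ggplot2::aes(y = .data$net_profit), colour = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$net_profit, group = 1),
                       colour = "red") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "USD per 10 a", fill = "Cultivar") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
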