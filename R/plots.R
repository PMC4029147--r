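#' Plot an attractor report
#'
#' Bar chart of basin sizes, one bar per attractor labelled by its state
#' bit-string; fixed points and limit cycles are distinguished by fill.
#'
#' @param object An `attractor_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.attractor_report <- function(object, ...) {
  a <- object$attractors
  ggplot2::ggplot(a, ggplot2::aes(
    x = stats::reorder(.data$state, -.data$basin_size),
    y = .data$basin_size, fill = .data$type
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "attractor state", y = "basin size", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a trajectory as a state heat-map
#'
#' Tile plot of node activity over time (dark = active), one row per
#' regulator in canonical order, annotated with the phase labels — the
#' visual analogue of a temporal-evolution table.
#'
#' @param object A `trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.trajectory <- function(object, ...) {
  nodes <- setdiff(names(object), c("time", "state", "phase"))
  long <- tidyr::pivot_longer(object[c("time", nodes)], -"time",
                              names_to = "node", values_to = "active")
  long$node <- factor(long$node, levels = rev(nodes))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$time), y = .data$node,
                                     fill = factor(.data$active))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "grey20"),
                               guide = "none") +
    ggplot2::labs(x = "time point", y = NULL) +
    ggplot2::theme_minimal()
}

#' Basin-size distribution on log-log axes
#'
#' Empirical probability of each pooled fixed-point basin size in a random
#' ensemble, drawn on log-log axes where a heavy tail shows as an
#' approximately straight descent. A reference basin size (e.g. the
#' biological network's 219) can be marked.
#'
#' @param stats An `ensemble_stats` object.
#' @param reference_basin Optional vertical marker; defaults to the
#'   reference basin stored in `stats`.
#' @return A ggplot.
#' @export
plot_basin_distribution <- function(stats,
                                    reference_basin = stats$reference_basin) {
  h <- basin_size_distribution(stats)
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$basin_size,
                                       y = .data$probability)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "basin size", y = "probability") +
    ggplot2::theme_minimal()
  if (!is.null(reference_basin)) {
    p <- p + ggplot2::geom_vline(xintercept = reference_basin,
                                 linetype = "dashed", colour = "blue")
  }
  p
}

#' Histogram of relative basin-size changes
#'
#' Probability mass of `delta_rel` from a perturbation scan; the spike at 0
#' is the share of perturbations that leave the largest attractor's basin
#' untouched, the robustness signature.
#'
#' @param results A [perturbation_scan()] tibble.
#' @return A ggplot.
#' @export
plot_delta_histogram <- function(results) {
  h <- delta_histogram(results)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$delta_rel,
                                  y = .data$probability)) +
    ggplot2::geom_col(width = 0.02) +
    ggplot2::labs(x = expression(Delta * B / B), y = "probability") +
    ggplot2::theme_minimal()
}
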