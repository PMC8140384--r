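# ggplot2 graphics for scan and detection objects.

#' Plot ROC curves of a percentile scan
#'
#' One curve per metric over the percentile grid, with the C1-optimal
#' operating point of each metric highlighted.
#'
#' @param object A `roc_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.roc_scan <- function(object, ...) {
  ggplot2::ggplot(object$curves,
                  ggplot2::aes(x = .data$fpr, y = .data$tpr,
                               colour = .data$metric)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = object$best_points, size = 3, shape = 21,
                        fill = "white") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate (sensitivity)",
                  colour = "Metric",
                  title = "Centroid-distance classifiers across percentile thresholds") +
    ggplot2::theme_minimal()
}

#' Plot the distance-to-centroid distribution of a detection run
#'
#' Per-metric distance histograms with the effective threshold marked;
#' rows beyond the line are the flagged anomalies.
#'
#' @param object A `detection_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.detection_result <- function(object, ...) {
  long <- object$rows |>
    dplyr::select("patient_id", dplyr::starts_with("dist_")) |>
    tidyr::pivot_longer(dplyr::starts_with("dist_"),
                        names_to = "metric", values_to = "distance",
                        names_prefix = "dist_")
  thr <- object$thresholds
  ggplot2::ggplot(long, ggplot2::aes(x = .data$distance)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(data = thr,
                        ggplot2::aes(xintercept = .data$effective_threshold),
                        colour = "red", linetype = "dashed") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "Distance to centroid", y = "Rows",
                  title = "Centroid distances and effective thresholds") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble-search ranking
#'
#' C2 criterion of the top-ranked metric combinations.
#'
#' @param x An `ensemble_search` tibble.
#' @param top_n How many combinations to show (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ensemble_ranking <- function(x, top_n = 10, ...) {
  top <- utils::head(x, top_n)
  top$combination <- stats::reorder(top$combination, top$c2)
  ggplot2::ggplot(top, ggplot2::aes(x = .data$c2, y = .data$combination)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "C2 = balanced accuracy + sensitivity",
                  y = "Metric combination",
                  title = "Union-rule ensemble ranking") +
    ggplot2::theme_minimal()
}
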