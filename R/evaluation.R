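# Performance evaluation against injected ground truth: confusion matrices,
# the eight performance measures, the C1 threshold-selection criterion, the
# C2 ensemble-selection criterion, the 81-point ROC percentile scan, and the
# exhaustive union-rule search over metric combinations.

#' Confusion matrix from predicted vs true anomalous rows
#'
#' @param predicted Integer vector of predicted anomalous row indices.
#' @param truth A `ground_truth` or integer vector of true anomalous rows.
#' @param n_rows Total number of rows scored.
#' @return One-row tibble `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(predicted, truth, n_rows) {
  pos <- if (inherits(truth, "ground_truth")) truth$anomalous_rows else truth
  pos <- as.integer(pos); predicted <- as.integer(predicted)
  if (length(pos) && max(pos) > n_rows) stop("truth rows outside the table")
  if (length(predicted) && max(predicted) > n_rows) {
    stop("predicted rows outside the table")
  }
  tp <- length(intersect(predicted, pos))
  fp <- length(setdiff(predicted, pos))
  fn <- length(setdiff(pos, predicted))
  tibble::tibble(TP = tp, FP = fp, TN = n_rows - tp - fp - fn, FN = fn)
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Performance measures of a confusion matrix
#'
#' Sensitivity, specificity, accuracy, balanced accuracy, precision, error
#' rate, Youden index (`sens + spec - 1`) and `ulc_dist`, the Euclidean
#' distance of the ROC point from the ideal upper-left corner
#' `sqrt((1-sens)^2 + (1-spec)^2)`.  Ratios with zero denominators are
#' defined as 0.
#'
#' @param cm One-row tibble (or list) with `TP`, `FP`, `TN`, `FN`.
#' @return One-row tibble of the eight measures.
#' @examples
#' perf_metrics(tibble::tibble(TP = 18, FP = 73, TN = 310, FN = 4))
#' @export
perf_metrics <- function(cm) {
  tp <- cm$TP; fp <- cm$FP; tn <- cm$TN; fn <- cm$FN
  sens <- safe_div(tp, tp + fn)
  spec <- safe_div(tn, tn + fp)
  total <- tp + fp + tn + fn
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    accuracy = safe_div(tp + tn, total),
    balanced_accuracy = (sens + spec) / 2,
    precision = safe_div(tp, tp + fp),
    error = safe_div(fp + fn, total),
    youden = sens + spec - 1,
    ulc_dist = sqrt((1 - sens)^2 + (1 - spec)^2)
  )
}

#' C2 ensemble-selection criterion
#'
#' Balanced accuracy plus sensitivity: `(TPR + TNR)/2 + TPR = (3 TPR +
#' TNR)/2`.  Favors sensitivity over specificity, the preference wanted
#' when a missed anomaly is costlier than a spurious query.
#'
#' @param sens,spec True positive and true negative rates in `[0, 1]`.
#' @return Numeric criterion value in `[0, 2]`.
#' @examples
#' c2_criterion(0.9546, 0.7937) # 1.829 to three decimals
#' @export
c2_criterion <- function(sens, spec) {
  stopifnot(all(sens >= 0 & sens <= 1), all(spec >= 0 & spec <= 1))
  (3 * sens + spec) / 2
}

#' C1 threshold-selection criterion over a candidate list
#'
#' Accuracy, Youden index and `ulc_dist` are each min-max normalized to
#' `[0, 1]` across the candidates (a constant member normalizes to 0 for
#' all), then `C1 = norm(acc)^2 + norm(youden)^2 - norm(ulc)^2`.  Larger is
#' better: high accuracy and Youden index, ROC point close to the ideal
#' corner.
#'
#' @param candidates Data frame with columns `accuracy`, `youden`,
#'   `ulc_dist` (one row per threshold candidate).
#' @return Numeric vector of C1 values, one per candidate.
#' @export
c1_criterion <- function(candidates) {
  stopifnot(nrow(candidates) >= 1L)
  norm01 <- function(x) {
    r <- range(x)
    if (r[[1L]] == r[[2L]]) rep(0, length(x)) else (x - r[[1L]]) / (r[[2L]] - r[[1L]])
  }
  norm01(candidates$accuracy)^2 + norm01(candidates$youden)^2 -
    norm01(candidates$ulc_dist)^2
}

#' Default ROC percentile grid
#'
#' 81 uniformly spaced percentiles from 5 to 95 inclusive.
#' @return Numeric vector of length 81.
#' @export
roc_grid <- function() seq(5, 95, length.out = 81)

#' ROC percentile scan with C1-based threshold selection
#'
#' For each metric and each grid percentile, rows are classified by the
#' effective threshold (minimum of the percentile threshold and the upper
#' Tukey fence) and scored against ground truth; the best percentile
#' maximizes C1 across the grid, ties resolved toward the lowest (most
#' sensitive) percentile.
#'
#' @param distances Numeric matrix (rows x metrics) of centroid distances,
#'   or the `rows` of a `detection_result` (its `dist_*` columns are used).
#' @param truth A `ground_truth` or integer vector of true anomalous rows.
#' @param grid Percentile grid (default [roc_grid()]).
#' @return A `roc_scan` object: list with `curves` (tibble: `metric`,
#'   `percentile`, `tpr`, `fpr`, the performance measures and `c1`) and
#'   `best` (per-metric tibble of the C1-optimal [compute_thresholds()]
#'   rows).
#' @export
roc_scan <- function(distances, truth, grid = roc_grid()) {
  if (length(grid) == 0L) stop("empty percentile grid")
  if (is.data.frame(distances)) {
    dcols <- grep("^dist_", names(distances), value = TRUE)
    m <- as.matrix(distances[, dcols])
    colnames(m) <- sub("^dist_", "", dcols)
    distances <- m
  }
  pos <- if (inherits(truth, "ground_truth")) truth$anomalous_rows else truth
  n <- nrow(distances)
  curves <- purrr::map_dfr(colnames(distances), function(k) {
    d <- distances[, k]
    per_p <- purrr::map_dfr(grid, function(p) {
      thr <- compute_thresholds(d, p, metric = k)
      pred <- which(d > thr$effective_threshold)
      cm <- confusion(pred, pos, n)
      perf <- perf_metrics(cm)
      dplyr::bind_cols(
        tibble::tibble(metric = k, percentile = p,
                       effective_threshold = thr$effective_threshold,
                       tpr = perf$sensitivity,
                       fpr = safe_div(cm$FP, cm$FP + cm$TN)),
        perf
      )
    })
    per_p$c1 <- c1_criterion(per_p)
    per_p
  })
  best <- curves |>
    dplyr::group_by(.data$metric) |>
    dplyr::arrange(dplyr::desc(.data$c1), .data$percentile, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  best_thr <- purrr::map_dfr(seq_len(nrow(best)), function(i) {
    compute_thresholds(distances[, best$metric[[i]]], best$percentile[[i]],
                       metric = best$metric[[i]])
  })
  structure(list(curves = curves, best = best_thr, best_points = best),
            class = "roc_scan")
}

#' @export
print.roc_scan <- function(x, ...) {
  cat(sprintf("<roc_scan> %d metric(s), %d grid point(s) each\n",
              dplyr::n_distinct(x$curves$metric),
              nrow(x$curves) / max(1L, dplyr::n_distinct(x$curves$metric))))
  print(x$best)
  invisible(x)
}

#' @export
tidy.roc_scan <- function(x, ...) x$curves

#' @export
glance.roc_scan <- function(x, ...) {
  dplyr::select(x$best_points, "metric", "percentile", "tpr", "fpr", "c1")
}

all_nonempty_subsets <- function(pool) {
  pool <- sort(pool)
  unlist(lapply(seq_along(pool), function(k) {
    utils::combn(pool, k, simplify = FALSE)
  }), recursive = FALSE)
}

#' Exhaustive union-rule search over metric combinations
#'
#' Evaluates every non-empty subset of the metric pool: a row is predicted
#' anomalous by a subset when at least one member metric flags it.  Subsets
#' are ranked by the C2 criterion (descending), ties broken by fewer
#' metrics, then lexicographic names.
#'
#' @param exceed_flags Logical matrix (rows x metrics) of per-metric exceed
#'   flags at fixed thresholds, or the `rows` of a `detection_result` (its
#'   `exceeds_*` columns are used).
#' @param truth A `ground_truth` or integer vector of true anomalous rows.
#' @param pool Metric codes to search over (default: the flag columns).
#' @return An `ensemble_search` tibble: `combination` (label), `metrics`
#'   (list-column), `n_metrics`, the performance measures and `c2`.
#' @export
ensemble_search <- function(exceed_flags, truth, pool = NULL) {
  if (is.data.frame(exceed_flags)) {
    fcols <- grep("^exceeds_", names(exceed_flags), value = TRUE)
    m <- as.matrix(exceed_flags[, fcols])
    colnames(m) <- sub("^exceeds_", "", fcols)
    exceed_flags <- m
  }
  if (is.null(pool)) pool <- colnames(exceed_flags)
  if (length(pool) == 0L) stop("empty metric pool")
  stopifnot(all(pool %in% colnames(exceed_flags)))
  pos <- if (inherits(truth, "ground_truth")) truth$anomalous_rows else truth
  n <- nrow(exceed_flags)
  res <- purrr::map_dfr(all_nonempty_subsets(pool), function(s) {
    pred <- which(rowSums(exceed_flags[, s, drop = FALSE]) > 0)
    perf <- perf_metrics(confusion(pred, pos, n))
    dplyr::bind_cols(
      tibble::tibble(combination = paste(s, collapse = "+"),
                     metrics = list(s), n_metrics = length(s)),
      perf
    )
  })
  res$c2 <- c2_criterion(res$sensitivity, res$specificity)
  res <- res[order(-res$c2, res$n_metrics, res$combination), ]
  structure(tibble::as_tibble(res), class = c("ensemble_search", class(res)))
}

#' Reconstruct a confusion matrix from reported rates
#'
#' Utility for auditing published performance tables: given sensitivity,
#' specificity and the cohort composition, recovers the integer confusion
#' counts by half-up rounding.
#'
#' @param sens,spec Rates in `[0, 1]`.
#' @param n_pos,n_neg Number of true anomalous and normal rows.
#' @return One-row tibble `TP`, `FP`, `TN`, `FN`.
#' @examples
#' reconstruct_confusion(0.8571, 0.7273, n_pos = 7, n_neg = 22)
#' @export
reconstruct_confusion <- function(sens, spec, n_pos, n_neg) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1)
  tp <- round_half_up(sens * n_pos)
  tn <- round_half_up(spec * n_neg)
  tibble::tibble(TP = tp, FP = n_neg - tn, TN = tn, FN = n_pos - tp)
}
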