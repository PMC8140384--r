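# Two-phase evaluation protocol: calibrate per-metric thresholds (ROC scan,
# C1) and the best union-rule ensemble (C2) on one data set, then validate
# the frozen configuration on an independent one.  Also the production
# detect -> query path over a whole registry.

#' Run configuration for the end-to-end pipeline
#'
#' @param preprocessing A [preprocess_config()].
#' @param metrics Active metric codes (default [default_metrics()]).
#' @param percentiles Default per-metric percentiles for self-thresholding.
#' @param mink_p,mah_ridge Minkowski exponent and Mahalanobis ridge.
#' @param simulation An [injection_config()].
#' @param grid ROC percentile grid (default [roc_grid()]).
#' @param seed Integer seed applied before any stochastic stage.
#' @return A `run_config` list, serializable to JSON.
#' @export
run_config <- function(preprocessing = preprocess_config(),
                       metrics = default_metrics(),
                       percentiles = default_percentiles(),
                       mink_p = 3, mah_ridge = 1e-6,
                       simulation = injection_config(),
                       grid = roc_grid(), seed = 1L) {
  if (length(metrics) == 0L) stop("empty metrics set in run configuration")
  structure(
    list(preprocessing = preprocessing, metrics = metrics,
         percentiles = percentiles, mink_p = mink_p, mah_ridge = mah_ridge,
         simulation = simulation, grid = grid, seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Calibrate thresholds and the metric ensemble on one data set
#'
#' Injects ground-truth anomalies into the clean table, scans the ROC
#' percentile grid per metric to pick C1-optimal thresholds, then searches
#' all metric combinations at those thresholds for the C2-best union-rule
#' ensemble.  Fully reproducible from the configuration seed.
#'
#' @param cal_table A clean `flat_table`.
#' @param cfg A [run_config()].
#' @return A `calibration` object: list with `thresholds` (per-metric
#'   [compute_thresholds()] rows at the C1-best percentiles), `percentiles`,
#'   `ensemble` (character vector of the C2-best combination), `roc` (the
#'   [roc_scan()]), `ensembles` (the full ranked [ensemble_search()] table)
#'   and `truth`.
#' @export
run_calibrate <- function(cal_table, cfg = run_config()) {
  set.seed(cfg$seed)
  sim_cfg <- cfg$simulation
  sim_cfg$rng_seed <- NULL                  # seeded once, above
  pm0 <- preprocess(cal_table, cfg$preprocessing, normalize = FALSE)
  sim <- simulate_anomalies(pm0, sim_cfg)
  pm <- pp_normalize(sim$table)
  det <- detect_anomalies(pm, metrics = cfg$metrics,
                          percentiles = cfg$percentiles,
                          mink_p = cfg$mink_p, mah_ridge = cfg$mah_ridge)
  dist_m <- as.matrix(det$rows[, paste0("dist_", cfg$metrics)])
  colnames(dist_m) <- cfg$metrics
  roc <- roc_scan(dist_m, sim$truth, grid = cfg$grid)
  flags <- sapply(cfg$metrics, function(k) {
    thr <- roc$best$effective_threshold[roc$best$metric == k]
    dist_m[, k] > thr
  })
  colnames(flags) <- cfg$metrics
  ens <- ensemble_search(flags, sim$truth, pool = cfg$metrics)
  structure(
    list(thresholds = roc$best,
         percentiles = stats::setNames(roc$best$percentile, roc$best$metric),
         ensemble = ens$metrics[[1L]],
         roc = roc, ensembles = ens, truth = sim$truth, config = cfg),
    class = "calibration"
  )
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> best ensemble {%s}; thresholds at percentiles %s\n",
              paste(x$ensemble, collapse = ", "),
              paste(sprintf("%s=%.1f", x$thresholds$metric,
                            x$thresholds$percentile), collapse = ", ")))
  invisible(x)
}

#' Serialize / restore a calibration artifact
#'
#' @param cal A `calibration`.
#' @param path JSON path.
#' @return Invisibly `path` (writer); a reduced `calibration` holding the
#'   frozen thresholds and ensemble (reader).
#' @export
write_calibration <- function(cal, path) {
  jsonlite::write_json(
    list(thresholds = cal$thresholds, ensemble = cal$ensemble,
         mink_p = cal$config$mink_p, mah_ridge = cal$config$mah_ridge),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  doc <- jsonlite::fromJSON(path)
  structure(
    list(thresholds = tibble::as_tibble(doc$thresholds),
         percentiles = stats::setNames(doc$thresholds$percentile,
                                       doc$thresholds$metric),
         ensemble = doc$ensemble,
         config = list(mink_p = doc$mink_p, mah_ridge = doc$mah_ridge)),
    class = "calibration"
  )
}

#' Validate a frozen calibration on an independent data set
#'
#' Applies the calibration's thresholds and ensemble to a new table with
#' known ground truth (thresholds from the calibration set, performance
#' measured on unseen data — the deployment-mimicking scenario).
#'
#' @param cal A `calibration`.
#' @param test_table A clean `flat_table` to corrupt and score, or an
#'   already-contaminated unnormalized `preproc_matrix` when `truth` is
#'   supplied.
#' @param truth Optional `ground_truth` matching `test_table`; when absent,
#'   anomalies are injected using `sim_cfg`.
#' @param sim_cfg An [injection_config()] for the injection (ignored when
#'   `truth` is given).
#' @param pre_cfg A [preprocess_config()].
#' @param threshold_mode `"percentile"` (default) re-applies the calibrated
#'   per-metric percentile values to the test table's own distance
#'   distribution (distance scales are table-specific, so percentile
#'   choices are what transfer across registries); `"absolute"` freezes the
#'   calibration's raw distance cut-offs, appropriate only when calibration
#'   and test tables share columns and scaling.
#' @return A `validation_report`: list with `confusion`, `perf` (the
#'   measures + `c2`), `ensemble`, `detection` and `truth`.
#' @export
run_validate <- function(cal, test_table, truth = NULL,
                         sim_cfg = injection_config(),
                         pre_cfg = preprocess_config(),
                         threshold_mode = c("percentile", "absolute")) {
  threshold_mode <- match.arg(threshold_mode)
  if (inherits(test_table, "preproc_matrix")) {
    if (is.null(truth)) stop("a contaminated matrix requires its ground truth")
    pm0 <- test_table
  } else {
    pm0 <- preprocess(test_table, pre_cfg, normalize = FALSE)
    if (is.null(truth)) {
      sim <- simulate_anomalies(pm0, sim_cfg)
      pm0 <- sim$table
      truth <- sim$truth
    }
  }
  if (length(truth$anomalous_rows) &&
      max(truth$anomalous_rows) > nrow(pm0$values)) {
    stop("ground truth refers to rows outside the test table")
  }
  pm <- pp_normalize(pm0)
  det <- if (threshold_mode == "percentile") {
    detect_anomalies(
      pm, metrics = cal$ensemble, percentiles = cal$percentiles,
      mink_p = cal$config$mink_p %||% 3,
      mah_ridge = cal$config$mah_ridge %||% 1e-6
    )
  } else {
    detect_anomalies(
      pm, metrics = cal$ensemble, thresholds = cal$thresholds,
      mink_p = cal$config$mink_p %||% 3,
      mah_ridge = cal$config$mah_ridge %||% 1e-6
    )
  }
  pred <- which(det$rows$anomalous)
  cm <- confusion(pred, truth, nrow(pm$values))
  perf <- perf_metrics(cm)
  perf$c2 <- c2_criterion(perf$sensitivity, perf$specificity)
  structure(
    list(confusion = cm, perf = perf, ensemble = cal$ensemble,
         detection = det, truth = truth),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> ensemble {%s}: sens %.1f%%, spec %.1f%%, C2 %.3f\n",
    paste(x$ensemble, collapse = ", "),
    100 * x$perf$sensitivity, 100 * x$perf$specificity, x$perf$c2
  ))
  invisible(x)
}

#' @export
tidy.validation_report <- function(x, ...) {
  dplyr::bind_cols(x$confusion, x$perf)
}

#' @export
glance.validation_report <- function(x, ...) {
  tibble::tibble(
    ensemble = paste(x$ensemble, collapse = "+"),
    sensitivity = x$perf$sensitivity, specificity = x$perf$specificity,
    c2 = x$perf$c2
  )
}

#' Production detection over a whole registry
#'
#' Runs the detector once on the prefix table and once per semi-flattened
#' table (`n_semiflattened + 1` runs), applies post-hoc univariate variable
#' flagging to every anomalous row, and aggregates per-patient queries
#' (max strength over a patient's rows, union of flagged variables).
#'
#' @param reg A `registry`.
#' @param cfg A [run_config()].
#' @param calibration Optional `calibration` with frozen thresholds;
#'   without it thresholds are computed from each scored table itself.
#' @return List with `queries` (tibble from [generate_queries()]),
#'   `detections` (one `detection_result` per run) and `runs` (count).
#' @export
run_detect <- function(reg, cfg = run_config(), calibration = NULL) {
  tables <- c(list(prefix = build_prefix_table(reg)),
              build_semiflattened_tables(reg))
  detections <- list(); flags <- list()
  for (nm in names(tables)) {
    pm <- preprocess(tables[[nm]], cfg$preprocessing)
    det <- if (is.null(calibration)) {
      detect_anomalies(pm, metrics = cfg$metrics,
                       percentiles = cfg$percentiles,
                       mink_p = cfg$mink_p, mah_ridge = cfg$mah_ridge)
    } else {
      detect_anomalies(pm, metrics = calibration$ensemble,
                       thresholds = calibration$thresholds,
                       mink_p = cfg$mink_p, mah_ridge = cfg$mah_ridge)
    }
    for (i in which(det$rows$anomalous)) {
      p <- det$rows$patient_id[[i]]
      flags[[length(flags) + 1L]] <- stats::setNames(
        list(posthoc_flag_variables(pm, i)), p
      )
    }
    detections[[nm]] <- det
  }
  flags <- purrr::flatten(flags)
  queries <- generate_queries(detections, flags)
  list(queries = queries, detections = detections, runs = length(tables))
}
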