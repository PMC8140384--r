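# Centroid-distance ensemble detection: every row of the preprocessed
# matrix is scored by its distance to the single global centroid under up to
# seven metrics; a row is anomalous when at least one metric's distance
# strictly exceeds min(percentile threshold, Tukey upper fence), and the
# number of exceeding metrics is the strength of evidence.

#' The seven supported distance metrics
#'
#' Canberra, Chebyshev, cosine, Euclidean, Manhattan, Mahalanobis and
#' Minkowski.
#' @format Character vector of metric codes.
#' @export
METRIC_KINDS <- c("CAN", "CHEB", "COS", "EUC", "MAN", "MAH", "MINK")

#' Default per-metric percentile thresholds
#'
#' Percentiles calibrated on a large evaluation registry; Chebyshev and
#' cosine are retained here for completeness but are excluded from the
#' default active set (see [detect_anomalies()]) because they performed
#' worst as single-metric classifiers.
#'
#' @return Named numeric vector of percentiles in `[0, 100]`.
#' @export
default_percentiles <- function() {
  c(CAN = 77.5, CHEB = 64.0, COS = 95.0, EUC = 86.0,
    MAH = 88.0, MAN = 86.0, MINK = 83.5)
}

#' Default active metric set
#'
#' Mahalanobis, Manhattan, Canberra, Euclidean and Minkowski; Chebyshev and
#' cosine are excluded.
#' @return Character vector of metric codes.
#' @export
default_metrics <- function() c("CAN", "EUC", "MAH", "MAN", "MINK")

#' Column-wise centroid of a preprocessed matrix
#'
#' All rows form a single cluster; its centroid is the arithmetic mean of
#' every column.
#'
#' @param m A `preproc_matrix` or numeric matrix.
#' @return Numeric vector, one entry per column.
#' @export
centroid <- function(m) {
  v <- if (inherits(m, "preproc_matrix")) m$values else m
  if (is.null(dim(v)) || nrow(v) < 1L) stop("centroid needs at least one row")
  colMeans(v)
}

#' Distance between two vectors under a named metric
#'
#' Conventions for degenerate terms: Canberra 0/0 terms contribute 0; cosine
#' distance is 1 when either vector has zero norm.
#'
#' @param x,y Numeric vectors of equal length, all finite.
#' @param kind One of [METRIC_KINDS].
#' @param p Minkowski exponent (default 3; 1 and 2 coincide with Manhattan
#'   and Euclidean).
#' @param inv_cov Inverse covariance matrix, required for `"MAH"`.
#' @return Non-negative scalar distance.
#' @examples
#' metric_distance(c(0, 0), c(3, 4), "EUC") # 5
#' @export
metric_distance <- function(x, y, kind, p = 3, inv_cov = NULL) {
  if (length(x) != length(y)) stop("dimension mismatch between x and y")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  kind <- match.arg(kind, METRIC_KINDS)
  d <- x - y
  switch(kind,
    CAN = {
      den <- abs(x) + abs(y)
      sum(ifelse(den == 0, 0, abs(d) / den))
    },
    CHEB = max(abs(d)),
    COS = {
      nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
      if (nx == 0 || ny == 0) 1 else 1 - sum(x * y) / (nx * ny)
    },
    EUC = sqrt(sum(d^2)),
    MAN = sum(abs(d)),
    MAH = {
      if (is.null(inv_cov)) stop("MAH requires inv_cov")
      sqrt(drop(t(d) %*% inv_cov %*% d))
    },
    MINK = sum(abs(d)^p)^(1 / p)
  )
}

#' Inverse covariance for the Mahalanobis metric
#'
#' Sample covariance of the matrix plus `ridge` on the diagonal, inverted;
#' if the regularized matrix is still numerically singular (e.g. constant
#' columns at ridge 0) the Moore-Penrose pseudo-inverse is used instead.
#' The route taken is recorded in the `"method"` attribute.
#'
#' @param m A `preproc_matrix` or numeric matrix with at least 2 rows.
#' @param ridge Non-negative diagonal regularizer (default 1e-6).
#' @return Inverse covariance matrix with attribute `method` =
#'   `"solve"` or `"pseudoinverse"`.
#' @export
mahalanobis_params <- function(m, ridge = 1e-6) {
  v <- if (inherits(m, "preproc_matrix")) m$values else m
  if (nrow(v) < 2L) stop("Mahalanobis covariance needs at least 2 rows")
  s <- stats::cov(v) + diag(ridge, ncol(v))
  inv <- tryCatch(solve(s), error = function(e) NULL)
  if (is.null(inv) || !all(is.finite(inv))) {
    inv <- MASS::ginv(s)
    attr(inv, "method") <- "pseudoinverse"
  } else {
    attr(inv, "method") <- "solve"
  }
  inv
}

# All rows' distances to the centroid: n x length(metrics) matrix.
centroid_distance_matrix <- function(values, center, metrics, p = 3,
                                     inv_cov = NULL) {
  d <- sweep(values, 2L, center)
  out <- sapply(metrics, function(k) {
    switch(k,
      CAN = {
        den <- sweep(abs(values), 2L, abs(center), `+`)
        terms <- abs(d) / den
        terms[den == 0] <- 0
        rowSums(terms)
      },
      CHEB = apply(abs(d), 1L, max),
      COS = {
        nx <- sqrt(rowSums(values^2)); nc <- sqrt(sum(center^2))
        res <- rep(1, nrow(values))
        ok <- nx > 0 & nc > 0
        res[ok] <- 1 - (values[ok, , drop = FALSE] %*% center) / (nx[ok] * nc)
        res
      },
      EUC = sqrt(rowSums(d^2)),
      MAN = rowSums(abs(d)),
      MAH = sqrt(pmax(rowSums((d %*% inv_cov) * d), 0)),
      MINK = rowSums(abs(d)^p)^(1 / p)
    )
  })
  out <- matrix(out, nrow = nrow(values), dimnames = list(NULL, metrics))
  out
}

#' Percentile and IQR thresholds for one metric's distance vector
#'
#' The percentile threshold uses linear-interpolation quantiles
#' (`stats::quantile` type 7); the IQR threshold is the upper Tukey fence
#' `Q3 + 1.5 * (Q3 - Q1)`; the effective threshold is the minimum of the
#' two.
#'
#' @param d Non-empty numeric vector of distances, all finite.
#' @param percentile Percentile in `[0, 100]`.
#' @param metric Metric code recorded in the result.
#' @return One-row tibble: `metric`, `percentile`, `percentile_threshold`,
#'   `iqr_threshold`, `effective_threshold`.
#' @export
compute_thresholds <- function(d, percentile, metric = NA_character_) {
  if (length(d) == 0L) stop("empty distance vector")
  if (!all(is.finite(d))) stop("non-finite distances")
  q <- stats::quantile(d, c(0.25, 0.75, percentile / 100),
                       type = 7, names = FALSE)
  pt <- q[[3L]]
  it <- q[[2L]] + 1.5 * (q[[2L]] - q[[1L]])
  tibble::tibble(
    metric = metric, percentile = percentile,
    percentile_threshold = pt, iqr_threshold = it,
    effective_threshold = min(pt, it)
  )
}

#' Detect anomalous rows by centroid distance
#'
#' Scores every row's distance to the global centroid under the active
#' metrics, thresholds each metric at `min(percentile threshold, upper
#' Tukey fence)` and applies the union rule: a row is anomalous when at
#' least one metric's distance strictly exceeds its effective threshold.
#' The strength of evidence is the number of exceeding metrics.
#'
#' Thresholds may be computed from the scored table itself (`thresholds =
#' NULL`, the default "self" mode) or frozen from an earlier calibration
#' (pass the `thresholds` tibble of a previous result or of
#' [run_calibrate()]), in which case only the percentile-vs-IQR minimum is
#' re-derived from the frozen values.
#'
#' @param pm A normalized `preproc_matrix`.
#' @param metrics Character vector of active metric codes (default
#'   [default_metrics()]).
#' @param percentiles Named numeric vector of per-metric percentiles
#'   (default [default_percentiles()]); used only in self mode.
#' @param thresholds Optional tibble with columns `metric` and
#'   `effective_threshold` to freeze thresholds.
#' @param mink_p Minkowski exponent (default 3).
#' @param mah_ridge Ridge for the Mahalanobis covariance (default 1e-6).
#' @return A `detection_result`: list with `rows` (tibble of row keys,
#'   per-metric distances `dist_*`, exceed flags `exceeds_*`, `strength`,
#'   `anomalous`), `thresholds`, `centroid`, `metrics`, and
#'   `threshold_mode` (`"self"` or `"calibrated"`).
#' @examples
#' reg <- generate_registry(synth_config(n_patients = 30, seed = 1))
#' det <- detect_anomalies(preprocess(build_prefix_table(reg)))
#' tidy(det)
#' @export
detect_anomalies <- function(pm, metrics = default_metrics(),
                             percentiles = default_percentiles(),
                             thresholds = NULL, mink_p = 3,
                             mah_ridge = 1e-6) {
  stopifnot(inherits(pm, "preproc_matrix"), isTRUE(pm$normalized))
  metrics <- match.arg(metrics, METRIC_KINDS, several.ok = TRUE)
  if (length(metrics) == 0L) stop("no active metrics")
  center <- centroid(pm)
  inv_cov <- if ("MAH" %in% metrics) mahalanobis_params(pm, mah_ridge)
  dm <- centroid_distance_matrix(pm$values, center, metrics, p = mink_p,
                                 inv_cov = inv_cov)
  if (is.null(thresholds)) {
    if (!all(metrics %in% names(percentiles))) {
      stop("no percentile configured for: ",
           paste(setdiff(metrics, names(percentiles)), collapse = ", "))
    }
    thr <- purrr::map_dfr(metrics, function(k) {
      compute_thresholds(dm[, k], percentiles[[k]], metric = k)
    })
    mode <- "self"
  } else {
    if (!all(metrics %in% thresholds$metric)) {
      stop("no threshold supplied for: ",
           paste(setdiff(metrics, thresholds$metric), collapse = ", "))
    }
    thr <- thresholds[match(metrics, thresholds$metric), ]
    mode <- "calibrated"
  }
  exceeds <- sweep(dm, 2L, thr$effective_threshold[match(colnames(dm), thr$metric)],
                   FUN = ">")
  strength <- rowSums(exceeds)
  rows <- dplyr::bind_cols(
    pm$row_keys,
    tibble::as_tibble(dm) |> rlang::set_names(paste0("dist_", colnames(dm))),
    tibble::as_tibble(exceeds) |> rlang::set_names(paste0("exceeds_", colnames(dm))),
    tibble::tibble(strength = as.integer(strength), anomalous = strength >= 1L)
  )
  structure(
    list(rows = rows, thresholds = thr, centroid = center, metrics = metrics,
         threshold_mode = mode, mink_p = mink_p, mah_ridge = mah_ridge),
    class = "detection_result"
  )
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf(
    "<detection_result> %d row(s), metrics {%s}, thresholds: %s; %d anomalous\n",
    nrow(x$rows), paste(x$metrics, collapse = ", "), x$threshold_mode,
    sum(x$rows$anomalous)
  ))
  invisible(x)
}

#' Tidy / summarize a detection result
#'
#' @param x A `detection_result`.
#' @param ... Unused.
#' @return `tidy()`: the per-row tibble of distances, exceed flags, strength
#'   and the anomaly flag. `glance()`: one-row summary.
#' @export
tidy.detection_result <- function(x, ...) x$rows

#' @rdname tidy.detection_result
#' @export
glance.detection_result <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x$rows), n_metrics = length(x$metrics),
    n_anomalous = sum(x$rows$anomalous),
    max_strength = if (nrow(x$rows)) max(x$rows$strength) else 0L,
    threshold_mode = x$threshold_mode
  )
}

#' Post-hoc univariate flagging of suspect variables for an anomalous row
#'
#' For each surviving column a Shapiro-Wilk test at level `alpha` decides
#' the branch: normally distributed columns flag the row's value when its
#' z-score magnitude exceeds `z_cut`; non-normal columns flag it when it
#' falls outside the Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`.
#'
#' @param pm A `preproc_matrix`.
#' @param row_key Either a row index or a list/tibble-row with `patient_id`
#'   and `instance_index`.
#' @param alpha Shapiro-Wilk level (default 0.05).
#' @param z_cut z-score cut-off for the normal branch (default 3).
#' @return Character vector of flagged qids (possibly empty).
#' @export
posthoc_flag_variables <- function(pm, row_key, alpha = 0.05, z_cut = 3) {
  stopifnot(inherits(pm, "preproc_matrix"))
  i <- if (is.numeric(row_key)) {
    as.integer(row_key)
  } else {
    which(pm$row_keys$patient_id == row_key$patient_id &
            (is.na(row_key$instance_index) & is.na(pm$row_keys$instance_index) |
               !is.na(pm$row_keys$instance_index) &
               pm$row_keys$instance_index %in% row_key$instance_index))[1L]
  }
  if (is.na(i) || i < 1L || i > nrow(pm$values)) stop("unknown row_key")
  flagged <- purrr::map_lgl(seq_along(pm$columns), function(j) {
    col <- pm$values[, j]
    v <- col[[i]]
    if (classify_normality(col, alpha = alpha) == "normal") {
      abs(v - mean(col)) > z_cut * stats::sd(col)
    } else {
      q <- stats::quantile(col, c(0.25, 0.75), type = 7, names = FALSE)
      iqr <- q[[2L]] - q[[1L]]
      v < q[[1L]] - 1.5 * iqr || v > q[[2L]] + 1.5 * iqr
    }
  })
  pm$columns[flagged]
}

#' Generate data-manager queries from detection results
#'
#' Aggregates anomalous rows back to patients: a patient's strength is the
#' maximum over their rows across all supplied runs (prefix + each
#' semi-flattened table) and their flagged variables are the union.
#' Output is ordered by strength (descending) then patient id.
#'
#' @param results A `detection_result` or list of them.
#' @param flags Optional named list mapping `"<patient_id>#<row index>"`-free
#'   patient ids to character vectors of flagged qids; most callers pass the
#'   result of running [posthoc_flag_variables()] over anomalous rows, named
#'   by patient id.
#' @return Tibble with `patient_id`, `strength`, `flagged_variables`
#'   (list-column) and a human-readable `message`.
#' @export
generate_queries <- function(results, flags = NULL) {
  if (inherits(results, "detection_result")) results <- list(results)
  rows <- purrr::map_dfr(results, function(r) {
    r$rows[, c("patient_id", "strength", "anomalous")]
  })
  flagged <- dplyr::filter(rows, .data$anomalous)
  if (nrow(flagged) == 0L) {
    return(tibble::tibble(patient_id = character(), strength = integer(),
                          flagged_variables = list(), message = character()))
  }
  anom <- flagged |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(strength = max(.data$strength), .groups = "drop")
  anom <- anom[order(-anom$strength, anom$patient_id), ]
  fv <- purrr::map(anom$patient_id, function(p) {
    sort(unique(unlist(flags[names(flags) == p])))
  })
  tibble::tibble(
    patient_id = anom$patient_id,
    strength = as.integer(anom$strength),
    flagged_variables = fv,
    message = sprintf(
      "Patient %s flagged as anomalous (strength of evidence %d/%s)%s",
      anom$patient_id, anom$strength,
      length(results[[1L]]$metrics),
      ifelse(lengths(fv) > 0L,
             paste0("; check variables: ", purrr::map_chr(fv, paste, collapse = ", ")),
             "")
    )
  )
}

#' Write queries as JSON lines
#'
#' One JSON object per line with keys `patient_id`, `strength`,
#' `flagged_variables`, `message`.  An empty query set writes an empty file.
#'
#' @param queries Tibble from [generate_queries()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_queries_jsonl <- function(queries, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(queries))) {
    writeLines(jsonlite::toJSON(
      list(patient_id = queries$patient_id[[i]],
           strength = queries$strength[[i]],
           flagged_variables = as.list(queries$flagged_variables[[i]]),
           message = queries$message[[i]]),
      auto_unbox = TRUE, digits = NA
    ), con)
  }
  invisible(path)
}
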