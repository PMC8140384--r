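# Four-step preprocessing of a flat table into a fully numeric, missing-free
# matrix on [0,1]: (1) drop over-missing and free-text variables, (2) impute
# (median for numeric-like, mode for boolean/categorical), (3) recode
# temporal and categorical variables to numbers, (4) min-max normalize.

TEMPORAL_DTYPES <- c("date", "datetime", "time")
NUMERIC_LIKE_DTYPES <- c("integer", "float", TEMPORAL_DTYPES)

#' Preprocessing configuration
#'
#' @param max_missing_fraction Variables whose missing-data fraction strictly
#'   exceeds this are dropped. Default 0.20.
#' @param epoch Reference instant for temporal recoding; temporal values
#'   become seconds elapsed since it. Default `"1600-01-01T00:00:01"` (UTC,
#'   proleptic Gregorian).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(max_missing_fraction = 0.20,
                              epoch = "1600-01-01T00:00:01") {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1)
  structure(list(max_missing_fraction = max_missing_fraction, epoch = epoch),
            class = "preprocess_config")
}

#' Drop unanalyzable variables
#'
#' Removes every `string`/`text` column (free-form notes) and every column
#' whose missing fraction strictly exceeds `max_missing_fraction`.
#'
#' @param t A `flat_table`.
#' @param cfg A [preprocess_config()].
#' @return List with the reduced `table` and a `drop_log` tibble
#'   (`qid`, `reason` = `"dtype"` or `"missing"`).
#' @export
drop_variables <- function(t, cfg = preprocess_config()) {
  if (nrow(t) == 0L) stop("flat table has no rows")
  dtypes <- ft_dtypes(t)
  qids <- ft_qids(t)
  reason <- purrr::map_chr(qids, function(q) {
    if (dtypes[[q]] %in% c("string", "text")) return("dtype")
    if (mean(is.na(t[[q]])) > cfg$max_missing_fraction) return("missing")
    NA_character_
  })
  drop_log <- tibble::tibble(qid = qids, reason = reason) |>
    dplyr::filter(!is.na(.data$reason))
  keep <- setdiff(qids, drop_log$qid)
  if (length(keep) == 0L) stop("no analyzable variables remain after dropping")
  kept <- new_flat_table(
    t[, c("patient_id", "instance_index", keep)],
    dtypes = dtypes[keep], kind = ft_kind(t), form_id = attr(t, "aqc_form")
  )
  list(table = kept, drop_log = drop_log)
}

mode_value <- function(x) {
  # most frequent observed value; ties -> lexicographically smallest
  tab <- table(as.character(x[!is.na(x)]))
  winners <- names(tab)[tab == max(tab)]
  sort(winners)[[1L]]
}

#' Impute missing cells
#'
#' Numeric-like columns (integer, float and temporal types, the latter via
#' their seconds-since-epoch representation) are filled with the column
#' median of observed values; boolean and categorical columns with the most
#' frequent observed value (ties broken by the lexicographically smallest
#' label).
#'
#' @inheritParams drop_variables
#' @return A `flat_table` with no missing cells.
#' @export
impute_missing <- function(t, cfg = preprocess_config()) {
  dtypes <- ft_dtypes(t)
  out <- t
  for (q in ft_qids(t)) {
    col <- t[[q]]
    miss <- is.na(col)
    if (!any(miss)) next
    if (all(miss)) stop(sprintf("column '%s' is entirely missing", q))
    dt <- dtypes[[q]]
    if (dt %in% c("integer", "float")) {
      col[miss] <- stats::median(col[!miss])
    } else if (dt %in% TEMPORAL_DTYPES) {
      secs <- recode_temporal(col[!miss], dtype = dt, epoch = cfg$epoch)
      col[miss] <- seconds_to_temporal(stats::median(secs), dtype = dt,
                                       epoch = cfg$epoch)
    } else {
      fill <- mode_value(col)
      col[miss] <- if (dt == "boolean") as.logical(fill) else fill
    }
    out[[q]] <- col
  }
  new_flat_table(out, dtypes = dtypes, kind = ft_kind(t),
                 form_id = attr(t, "aqc_form"))
}

epoch_seconds <- function(epoch) {
  as.numeric(as.POSIXct(sub("T", " ", epoch), tz = "UTC"))
}

#' Recode temporal values to seconds since the epoch
#'
#' Dates, datetimes and times become the number of seconds elapsed since the
#' reference epoch (default 1600-01-01T00:00:01), on the proleptic Gregorian
#' calendar with no timezone.  Pure dates count from midnight of that day;
#' pure times are placed on the epoch's own day.
#'
#' @param v Character vector of ISO-8601 values (`YYYY-MM-DD`,
#'   `YYYY-MM-DDTHH:MM:SS`, or `HH:MM:SS`).
#' @param dtype One of `"date"`, `"datetime"`, `"time"`.
#' @param epoch Reference instant, see [preprocess_config()].
#' @return Numeric vector of seconds (strictly increasing in time).
#' @examples
#' recode_temporal("1600-01-01T00:00:11", "datetime") # 10
#' @export
recode_temporal <- function(v, dtype = c("datetime", "date", "time"),
                            epoch = "1600-01-01T00:00:01") {
  dtype <- match.arg(dtype)
  iso <- switch(dtype,
    date = paste0(v, "T00:00:00"),
    time = paste0("1600-01-01T", v),
    datetime = v
  )
  parsed <- tryCatch(
    as.POSIXct(sub("T", " ", iso), tz = "UTC",
               tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M")),
    error = function(e) rep(as.POSIXct(NA), length(iso))
  )
  if (anyNA(parsed) && !anyNA(v)) {
    bad <- v[is.na(parsed)][[1L]]
    stop(sprintf("cannot parse %s value '%s'", dtype, bad), call. = FALSE)
  }
  as.numeric(parsed) - epoch_seconds(epoch)
}

#' @rdname recode_temporal
#' @param secs Numeric seconds since the epoch.
#' @export
seconds_to_temporal <- function(secs, dtype = c("datetime", "date", "time"),
                                epoch = "1600-01-01T00:00:01") {
  dtype <- match.arg(dtype)
  inst <- as.POSIXct(secs + epoch_seconds(epoch),
                     origin = "1970-01-01", tz = "UTC")
  switch(dtype,
    datetime = format(inst, "%Y-%m-%dT%H:%M:%S"),
    date = format(inst, "%Y-%m-%d"),
    time = format(inst, "%H:%M:%S")
  )
}

#' Recode a label column to integer codes by ascending frequency
#'
#' Unique labels get codes `0..k-1`, the least frequent label receiving 0;
#' frequency ties are broken by lexicographic label order.  With two labels
#' where one dominates (e.g. five `"Female"` vs two `"Male"`), the rarer
#' label codes to 0 and the commoner to 1.
#'
#' @param col Character (or logical) vector of observed labels, no missing.
#' @return List with integer `codes` and the named `map` (label -> code).
#' @export
recode_categorical <- function(col) {
  lab <- as.character(col)
  stopifnot(length(lab) >= 1L, !anyNA(lab))
  tab <- table(lab)
  ord <- order(as.integer(tab), names(tab))   # frequency asc, then label asc
  map <- stats::setNames(seq_along(ord) - 1L, names(tab)[ord])
  list(codes = unname(map[lab]), map = map)
}

#' Min-max normalize a numeric column to [0, 1]
#'
#' @param col Numeric vector, no missing values.
#' @return List with `values` (normalized column; all 0 when the column is
#'   constant) and `range` = `c(min, max)` used.
#' @export
normalize_minmax <- function(col) {
  stopifnot(is.numeric(col), !anyNA(col))
  rng <- range(col)
  vals <- if (rng[[1L]] == rng[[2L]]) rep(0, length(col)) else {
    (col - rng[[1L]]) / (rng[[2L]] - rng[[1L]])
  }
  list(values = vals, range = rng)
}

#' Preprocess a flat table into a numeric feature matrix
#'
#' Applies, in order: variable dropping, imputation, recoding (temporal to
#' seconds since epoch, boolean/categorical to frequency-ranked integer
#' codes) and, unless `normalize = FALSE`, per-column min-max normalization.
#' The rows of the result are the feature vectors from which the global
#' centroid is computed.
#'
#' @param t A `flat_table`.
#' @param cfg A [preprocess_config()].
#' @param normalize Set to `FALSE` to stop after recoding (the
#'   anomaly-injection simulator operates on this unnormalized stage);
#'   finish later with [pp_normalize()].
#' @return A `preproc_matrix`: list with `values` (numeric matrix), `columns`
#'   (surviving qids), `dtypes`, `row_keys` (tibble `patient_id`,
#'   `instance_index`), `recode_maps`, `column_ranges` (`NULL` until
#'   normalized), `drop_log`, and `normalized` flag.
#' @examples
#' reg <- generate_registry(synth_config(n_patients = 20, seed = 1))
#' pm <- preprocess(build_prefix_table(reg))
#' range(pm$values)
#' @export
preprocess <- function(t, cfg = preprocess_config(), normalize = TRUE) {
  dropped <- drop_variables(t, cfg)
  tt <- impute_missing(dropped$table, cfg)
  dtypes <- ft_dtypes(tt)
  qids <- ft_qids(tt)
  recode_maps <- list()
  cols <- lapply(qids, function(q) {
    dt <- dtypes[[q]]
    if (dt %in% c("integer", "float")) {
      as.numeric(tt[[q]])
    } else if (dt %in% TEMPORAL_DTYPES) {
      recode_temporal(as.character(tt[[q]]), dtype = dt, epoch = cfg$epoch)
    } else {
      rc <- recode_categorical(tt[[q]])
      recode_maps[[q]] <<- rc$map
      as.numeric(rc$codes)
    }
  })
  values <- do.call(cbind, cols)
  colnames(values) <- qids
  pm <- structure(
    list(
      values = values, columns = qids, dtypes = dtypes,
      row_keys = tt[, c("patient_id", "instance_index")],
      recode_maps = recode_maps, column_ranges = NULL,
      drop_log = dropped$drop_log, normalized = FALSE, config = cfg
    ),
    class = "preproc_matrix"
  )
  if (normalize) pp_normalize(pm) else pm
}

#' @rdname preprocess
#' @param pm An unnormalized `preproc_matrix`.
#' @export
pp_normalize <- function(pm) {
  stopifnot(inherits(pm, "preproc_matrix"))
  if (isTRUE(pm$normalized)) return(pm)
  ranges <- list()
  for (j in seq_len(ncol(pm$values))) {
    nm <- normalize_minmax(pm$values[, j])
    pm$values[, j] <- nm$values
    ranges[[pm$columns[[j]]]] <- nm$range
  }
  pm$column_ranges <- ranges
  pm$normalized <- TRUE
  pm
}

#' @export
print.preproc_matrix <- function(x, ...) {
  cat(sprintf(
    "<preproc_matrix> %d row(s) x %d column(s)%s; %d dropped variable(s)\n",
    nrow(x$values), ncol(x$values),
    if (x$normalized) ", normalized to [0,1]" else " (unnormalized)",
    nrow(x$drop_log)
  ))
  invisible(x)
}

#' Tidy a preprocessed matrix into a tibble
#'
#' @param x A `preproc_matrix`.
#' @param ... Unused.
#' @return Tibble: row keys followed by one numeric column per surviving qid.
#' @export
tidy.preproc_matrix <- function(x, ...) {
  dplyr::bind_cols(x$row_keys, tibble::as_tibble(x$values))
}

#' @rdname tidy.preproc_matrix
#' @export
glance.preproc_matrix <- function(x, ...) {
  tibble::tibble(
    n_rows = nrow(x$values), n_columns = ncol(x$values),
    n_dropped = nrow(x$drop_log), normalized = x$normalized
  )
}

#' Serialize preprocessing metadata to JSON
#'
#' Records the drop log, recode maps and normalization ranges so a
#' calibrated preprocessing can be audited or re-applied to new exports.
#'
#' @param pm A `preproc_matrix`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_preprocess_meta <- function(pm, path) {
  jsonlite::write_json(
    list(
      columns = pm$columns,
      dtypes = as.list(pm$dtypes[pm$columns]),
      drop_log = pm$drop_log,
      recode_maps = lapply(pm$recode_maps, as.list),
      column_ranges = pm$column_ranges,
      normalized = pm$normalized
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
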