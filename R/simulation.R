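# Ground-truth anomaly injection: a small fraction of cells in a clean
# (dropped/imputed/recoded, NOT normalized) table is rewritten, spread over a
# set of anomalous subjects.  Normally distributed variables are shifted to
# mean +/- 6 SD; non-normal variables receive draws from the interval spanned
# by their rare values (observed frequency < 10%).

round_half_up <- function(x) floor(x + 0.5)

#' Anomaly-injection configuration
#'
#' @param cell_fraction Fraction of eligible cells to change (default 0.01).
#' @param n_subjects Number of anomalous subjects, or `"random"` to draw it
#'   uniformly from `1..min(n_rows, Nc)`.
#' @param rng_seed Optional integer seed; when given, planning and injection
#'   are deterministic.
#' @param shapiro_alpha Level of the Shapiro-Wilk normality split (default
#'   0.05).
#' @param rare_freq_cut Relative-frequency cut below which an observed value
#'   counts as rare (default 0.10).
#' @param sigma_multiplier Shift size, in column SDs, for normally
#'   distributed variables (default 6).
#' @return An `injection_config` list.
#' @export
injection_config <- function(cell_fraction = 0.01, n_subjects = "random",
                             rng_seed = NULL, shapiro_alpha = 0.05,
                             rare_freq_cut = 0.10, sigma_multiplier = 6) {
  stopifnot(cell_fraction > 0, cell_fraction < 1,
            rare_freq_cut > 0, rare_freq_cut < 1)
  structure(
    list(cell_fraction = cell_fraction, n_subjects = n_subjects,
         rng_seed = rng_seed, shapiro_alpha = shapiro_alpha,
         rare_freq_cut = rare_freq_cut, sigma_multiplier = sigma_multiplier),
    class = "injection_config"
  )
}

eligible_columns <- function(pm) {
  pm$columns[pm$dtypes[pm$columns] %in% NUMERIC_LIKE_DTYPES]
}

#' Plan which cells to corrupt
#'
#' `Nc` (cells to change) is `cell_fraction` of all eligible cells, rounded
#' half-up with a floor of 1; `Ns` subjects are chosen (drawn uniformly when
#' `"random"`); each subject gets about `Nv = Nc/Ns` target cells in
#' eligible columns (integer, float, date, time, datetime), with the last
#' subject absorbing the remainder.
#'
#' @param pm An unnormalized `preproc_matrix` (dropped/imputed/recoded).
#' @param cfg An [injection_config()].
#' @return An `injection_plan`: list with `Nc`, `Ns`, `Nv` and a
#'   `target_cells` tibble (`row`, `qid`).
#' @export
plan_injection <- function(pm, cfg = injection_config()) {
  stopifnot(inherits(pm, "preproc_matrix"))
  if (isTRUE(pm$normalized)) {
    stop("injection operates on the unnormalized stage; use preprocess(normalize = FALSE)")
  }
  if (!is.null(cfg$rng_seed)) set.seed(cfg$rng_seed)
  n <- nrow(pm$values)
  if (n < 2L) stop("need at least 2 rows")
  elig <- eligible_columns(pm)
  if (length(elig) == 0L) stop("no eligible columns (integer/float/temporal)")
  nc <- max(1L, round_half_up(cfg$cell_fraction * n * length(elig)))
  ns <- if (identical(cfg$n_subjects, "random")) {
    sample.int(min(n, nc), 1L)
  } else {
    as.integer(cfg$n_subjects)
  }
  if (ns > n) stop("n_subjects exceeds row count")
  nv <- max(1L, round_half_up(nc / ns))
  counts <- rep(nv, ns)
  counts[ns] <- nc - nv * (ns - 1L)
  counts <- pmin(pmax(counts, 1L), length(elig))
  subjects <- sample.int(n, ns)
  cells <- purrr::map2_dfr(subjects, counts, function(row, k) {
    tibble::tibble(row = row, qid = sample(elig, k))
  })
  structure(list(Nc = nrow(cells), Ns = ns, Nv = nv, target_cells = cells),
            class = "injection_plan")
}

#' Classify a column as normal or non-normal
#'
#' Shapiro-Wilk at level `alpha`; columns with fewer than 3 distinct values
#' (where the test is undefined) are non-normal by decision, as are columns
#' longer than the test's 5000-observation limit after down-sampling is not
#' attempted (the first 5000 values are used).
#'
#' @param col Numeric vector.
#' @param alpha Test level (default 0.05).
#' @return `"normal"` or `"non_normal"`.
#' @export
classify_normality <- function(col, alpha = 0.05) {
  col <- col[is.finite(col)]
  if (length(unique(col)) < 3L) return("non_normal")
  if (length(col) > 5000L) col <- col[seq_len(5000L)]
  p <- stats::shapiro.test(col)$p.value
  if (p >= alpha) "normal" else "non_normal"
}

#' Injected value for a normally distributed column
#'
#' Returns `mean + s * sigma_multiplier * sd` with the sign `s` chosen
#' uniformly at random, i.e. a 6-sigma shift by default.
#'
#' @param mean,sd Column mean and standard deviation (`sd > 0`).
#' @param cfg An [injection_config()].
#' @return Scalar injected value.
#' @export
inject_value_normal <- function(mean, sd, cfg = injection_config()) {
  stopifnot(sd > 0)
  s <- sample(c(-1, 1), 1L)
  mean + s * cfg$sigma_multiplier * sd
}

#' Injected value for a non-normally distributed column
#'
#' The rare set is the observed values with relative frequency below
#' `rare_freq_cut`; the injected value is drawn uniformly from the closed
#' interval they span (rounded for integer and temporal dtypes).  When no
#' value is rare (e.g. a constant column) the fallback is
#' `max(col) + 3 * IQR`, bumped above the maximum if the IQR is 0.
#'
#' @param col Numeric column (recoded, unnormalized).
#' @param cfg An [injection_config()].
#' @param dtype Column dtype, used for integer rounding.
#' @return Scalar injected value.
#' @export
inject_value_rare <- function(col, cfg = injection_config(), dtype = "float") {
  ux <- unique(col)
  cnt <- tabulate(match(col, ux))
  rare <- ux[cnt / length(col) < cfg$rare_freq_cut]
  if (length(rare) == 0L) {
    q <- stats::quantile(col, c(0.25, 0.75), type = 7, names = FALSE)
    v <- max(col) + 3 * (q[[2L]] - q[[1L]])
    if (v <= max(col)) v <- max(col) + max(1, 0.1 * abs(max(col)))
  } else {
    v <- stats::runif(1L, min(rare), max(rare))
  }
  if (dtype %in% c("integer", TEMPORAL_DTYPES)) v <- round_half_up(v)
  v
}

#' Inject simulated anomalies into a clean table
#'
#' Replaces each planned target cell according to its column's normality
#' branch (6-sigma shift vs rare-interval draw).  An optional edit-check
#' predicate `function(qid, value)` models the registry's automatic
#' validation: rejected draws are retried up to 10 times, then skipped with
#' a log entry, mirroring values entered through the EDC's own checks.
#'
#' @param pm An unnormalized `preproc_matrix`.
#' @param cfg An [injection_config()].
#' @param edit_check Optional predicate `(qid, value) -> TRUE/FALSE`.
#' @param plan Optional pre-computed [plan_injection()] result.
#' @return List with `table` (the corrupted `preproc_matrix`) and `truth`
#'   (a `ground_truth`: `anomalous_rows` indices, `changes` tibble with
#'   `row`, `patient_id`, `qid`, `old`, `new`, and a `skipped` tibble).
#' @examples
#' tbl <- generate_clean_matrix(29, 6, seed = 1)
#' sim <- simulate_anomalies(preprocess(tbl, normalize = FALSE),
#'                           injection_config(n_subjects = 7, rng_seed = 1))
#' length(sim$truth$anomalous_rows)
#' @export
simulate_anomalies <- function(pm, cfg = injection_config(),
                               edit_check = NULL, plan = NULL) {
  stopifnot(inherits(pm, "preproc_matrix"), !isTRUE(pm$normalized))
  if (is.null(plan)) plan <- plan_injection(pm, cfg)
  branch <- purrr::map_chr(
    stats::setNames(pm$columns, pm$columns),
    function(q) {
      col <- pm$values[, q]
      if (stats::sd(col) == 0) return("non_normal")
      classify_normality(col, alpha = cfg$shapiro_alpha)
    }
  )
  changes <- list(); skipped <- list()
  vals <- pm$values
  for (i in seq_len(nrow(plan$target_cells))) {
    row <- plan$target_cells$row[[i]]
    qid <- plan$target_cells$qid[[i]]
    col <- pm$values[, qid]       # pre-injection column statistics
    old <- vals[row, qid]
    new <- NA_real_
    for (try in seq_len(10L)) {
      cand <- if (branch[[qid]] == "normal") {
        inject_value_normal(mean(col), stats::sd(col), cfg)
      } else {
        inject_value_rare(col, cfg, dtype = pm$dtypes[[qid]])
      }
      if (is.null(edit_check) || isTRUE(edit_check(qid, cand))) {
        new <- cand
        break
      }
    }
    if (is.na(new)) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(row = row, qid = qid)
      next
    }
    vals[row, qid] <- new
    changes[[length(changes) + 1L]] <- tibble::tibble(
      row = row, patient_id = pm$row_keys$patient_id[[row]],
      qid = qid, old = old, new = new
    )
  }
  changes <- if (length(changes)) dplyr::bind_rows(changes) else {
    tibble::tibble(row = integer(), patient_id = character(),
                   qid = character(), old = numeric(), new = numeric())
  }
  skipped <- if (length(skipped)) dplyr::bind_rows(skipped) else {
    tibble::tibble(row = integer(), qid = character())
  }
  pm$values <- vals
  truth <- structure(
    list(anomalous_rows = sort(unique(changes$row)), changes = changes,
         skipped = skipped, plan = plan, config = cfg),
    class = "ground_truth"
  )
  list(table = pm, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d change(s) across %d anomalous row(s); %d skipped by edit checks\n",
    nrow(x$changes), length(x$anomalous_rows), nrow(x$skipped)
  ))
  invisible(x)
}

#' Write / read ground truth as JSON
#'
#' @param truth A `ground_truth`.
#' @param path JSON path.
#' @return Invisibly `path` (writer); a `ground_truth` (reader).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(
    list(anomalous_rows = truth$anomalous_rows,
         changes = truth$changes,
         config = unclass(truth$config)),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  doc <- jsonlite::fromJSON(path)
  structure(
    list(anomalous_rows = as.integer(doc$anomalous_rows),
         changes = tibble::as_tibble(doc$changes),
         skipped = tibble::tibble(row = integer(), qid = character()),
         plan = NULL, config = doc$config),
    class = "ground_truth"
  )
}
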