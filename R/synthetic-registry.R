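# Seeded synthetic registries: clean fixtures with the structural shape the
# detector assumes (mixed eCRF data types, repeating forms, configurable
# missingness), so the whole pipeline is testable without access to any
# real registry export.

#' Synthetic-registry configuration
#'
#' Two named profiles mirror the cohort sizes used throughout the package's
#' evaluation examples: `"registry3-like"` (405 patients, the larger
#' calibration-scale cohort) and `"registry5-like"` (29 patients, the small
#' validation-scale cohort).
#'
#' @param n_patients Number of patients (>= 2).
#' @param profile Optional profile name; sets `n_patients` when given.
#' @param n_extra_numeric Extra numeric questions on the subject form, on
#'   top of the fixed all-nine-dtypes block.
#' @param missingness Per-cell missingness rate in `[0, 1)` (default 0.05).
#' @param followup_lambda Mean (Poisson) number of repeating follow-up form
#'   instances per patient (default 1.5).
#' @param seed Integer seed; all generation is deterministic given it.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_patients = 29,
                         profile = NULL,
                         n_extra_numeric = 4,
                         missingness = 0.05,
                         followup_lambda = 1.5,
                         seed = 1L) {
  if (!is.null(profile)) {
    n_patients <- switch(match.arg(profile, c("registry3-like", "registry5-like")),
                         "registry3-like" = 405L, "registry5-like" = 29L)
  }
  stopifnot(n_patients >= 2, missingness >= 0, missingness < 1)
  structure(
    list(n_patients = as.integer(n_patients),
         n_extra_numeric = n_extra_numeric,
         missingness = missingness, followup_lambda = followup_lambda,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

rand_date <- function(n, from = "1935-01-01", to = "1995-12-31") {
  d0 <- as.Date(from); d1 <- as.Date(to)
  format(d0 + sample.int(as.integer(d1 - d0), n, replace = TRUE), "%Y-%m-%d")
}

maybe_missing <- function(x, rate) {
  x[stats::runif(length(x)) < rate] <- NA
  x
}

#' Generate a synthetic registry
#'
#' Emits a registry with two single-instance forms (subject demographics
#' covering all nine data types plus extra numeric questions; a
#' hospitalization form) and two repeating forms (follow-up with
#' Poisson-distributed instance counts; quality-of-life present for a random
#' subset of patients), with missing cells injected at the configured rate.
#' Deterministic for a fixed seed.
#'
#' @param cfg A [synth_config()].
#' @return A `registry` (see [load_registry()]).
#' @examples
#' reg <- generate_registry(synth_config(n_patients = 10, seed = 42))
#' n_detection_runs(reg) # 3: prefix + 2 repeating forms
#' @export
generate_registry <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  n <- cfg$n_patients
  pid <- sprintf("%07d", sample.int(9999999L, n))

  q <- function(form, grp, k) sprintf("A0.P0.F%s.G%s.Q%d", form, grp, k)
  extra <- if (cfg$n_extra_numeric > 0) {
    stats::setNames(
      lapply(seq_len(cfg$n_extra_numeric), function(j) {
        if (j %% 2 == 0) round(stats::rnorm(n, 50 + 5 * j, 4 + j), 1)
        else round(stats::rexp(n, 1 / (10 + j)), 1)
      }),
      q(1, 3, seq_len(cfg$n_extra_numeric))
    )
  } else list()
  extra_dtypes <- stats::setNames(rep("float", length(extra)), names(extra))

  rand_time <- function(k) {
    sprintf("%02d:%02d:%02d", sample(0:23, k, TRUE), sample(0:59, k, TRUE),
            sample(0:59, k, TRUE))
  }
  # all nine dtypes appear on the subject form
  subj_vals <- list(
    sample(LETTERS, n, replace = TRUE),
    paste("note", sample.int(1e6, n)),
    sample(18:88, n, replace = TRUE),
    round(stats::rnorm(n, 70, 12), 1),
    rand_date(n),
    paste0(rand_date(n, "2015-01-01", "2020-12-31"), "T", rand_time(n)),
    rand_time(n),
    sample(c(TRUE, FALSE), n, TRUE, prob = c(0.7, 0.3)),
    sample(c("Female", "Male"), n, TRUE, prob = c(0.6, 0.4))
  )
  names(subj_vals) <- q(1, 1, 1:9)
  subject <- list(
    values = c(subj_vals, extra),
    dtypes = c(stats::setNames(
      c("string", "text", "integer", "float", "date", "datetime", "time",
        "boolean", "categorical"),
      q(1, 1, 1:9)
    ), extra_dtypes)
  )
  hosp <- list(
    values = stats::setNames(list(
      sample.int(30L, n, replace = TRUE),
      round(stats::rlnorm(n, 2, 0.4), 1)
    ), q(2, 1, 1:2)),
    dtypes = stats::setNames(c("integer", "float"), q(2, 1, 1:2))
  )

  mk_questions <- function(form_id, dtypes) {
    purrr::imap(dtypes, function(dt, qid) list(qid = qid, dtype = dt))
  }
  fu_q <- stats::setNames(c("date", "float", "categorical"), q(3, 1, 1:3))
  qol_q <- stats::setNames(c("integer", "integer"), q(4, 1, 1:2))

  structure_doc <- list(forms = list(
    list(form_id = "subject", repeatable = FALSE,
         questions = unname(mk_questions("subject", subject$dtypes))),
    list(form_id = "hospitalization", repeatable = FALSE,
         questions = unname(mk_questions("hospitalization", hosp$dtypes))),
    list(form_id = "followup", repeatable = TRUE,
         questions = unname(mk_questions("followup", fu_q))),
    list(form_id = "qol", repeatable = TRUE,
         questions = unname(mk_questions("qol", qol_q)))
  ))

  cell <- function(v) {
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      list(value = NULL, state = "missing")
    } else list(value = v, state = "done")
  }
  form_answers <- function(values, dtypes, i) {
    cells <- purrr::imap(values, function(col, qid) {
      v <- maybe_missing(col[i], cfg$missingness)
      cell(if (is.na(v)) NA else v)
    })
    cells
  }

  n_fu <- stats::rpois(n, cfg$followup_lambda)
  has_qol <- stats::runif(n) < 0.6

  patients <- lapply(seq_len(n), function(i) {
    forms <- list(
      list(form_id = "subject", instance_index = 1L,
           answers = form_answers(subject$values, subject$dtypes, i)),
      list(form_id = "hospitalization", instance_index = 1L,
           answers = form_answers(hosp$values, hosp$dtypes, i))
    )
    for (j in seq_len(n_fu[[i]])) {
      fu_vals <- list(rand_date(1, "2016-01-01", "2021-12-31"),
                      round(stats::rnorm(1, 65, 10), 1),
                      sample(c("stable", "improved", "worse"), 1,
                             prob = c(0.6, 0.3, 0.1)))
      names(fu_vals) <- names(fu_q)
      forms[[length(forms) + 1L]] <- list(
        form_id = "followup", instance_index = j,
        answers = purrr::imap(fu_vals, function(v, qid) {
          vv <- maybe_missing(v, cfg$missingness)
          cell(if (is.na(vv)) NA else vv)
        })
      )
    }
    if (has_qol[[i]]) {
      qv <- list(sample(0:100, 1), sample(1:5, 1))
      names(qv) <- names(qol_q)
      forms[[length(forms) + 1L]] <- list(
        form_id = "qol", instance_index = 1L,
        answers = purrr::imap(qv, function(v, qid) cell(v))
      )
    }
    list(patient_id = pid[[i]], forms = forms)
  })

  load_registry(structure_doc, list(patients = patients))
}

#' Generate a clean numeric table for simulation studies
#'
#' A flat table of `n_cols` fully observed numeric variables over `n_rows`
#' synthetic patients: a configurable share of columns is Gaussian (so the
#' Shapiro-Wilk split takes the normal branch) and the rest exponential
#' (skewed, non-normal branch).  No anomalies are present.
#'
#' @param n_rows Number of rows (>= 2).
#' @param n_cols Number of numeric columns.
#' @param prop_normal Share of Gaussian columns (default 0.5).
#' @param seed Integer seed.
#' @return A `flat_table` of kind `"prefix"` with float dtypes.
#' @examples
#' tbl <- generate_clean_matrix(29, 10, prop_normal = 1, seed = 7)
#' @export
generate_clean_matrix <- function(n_rows, n_cols, prop_normal = 0.5,
                                  seed = 1L) {
  stopifnot(n_rows >= 2, n_cols >= 1)
  set.seed(seed)
  n_norm <- round(prop_normal * n_cols)
  cols <- lapply(seq_len(n_cols), function(j) {
    if (j <= n_norm) stats::rnorm(n_rows, mean = 10 * j, sd = 1 + j / 4)
    else stats::rexp(n_rows, rate = 1 / (5 + j))
  })
  qids <- sprintf("A0.P0.F1.G1.Q%d", seq_len(n_cols))
  names(cols) <- qids
  data <- dplyr::bind_cols(
    tibble::tibble(patient_id = sprintf("S%04d", seq_len(n_rows)),
                   instance_index = NA_integer_),
    tibble::as_tibble(cols)
  )
  new_flat_table(data, dtypes = stats::setNames(rep("float", n_cols), qids),
                 kind = "prefix")
}
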