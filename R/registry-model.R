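# EAV registry data model: arms -> phases -> forms -> question groups ->
# questions -> answers.  A registry is loaded from two JSON documents (a
# structure description and a per-patient answers export) and flattened into
# wide tables on which detection operates.

#' Question data types supported by the registry model
#'
#' @format Character vector of the nine electronic case report form (eCRF)
#'   data types a question may take.
#' @export
REGISTRY_DTYPES <- c(
  "string", "text", "integer", "float",
  "date", "datetime", "time", "boolean", "categorical"
)

#' Read a JSON document, failing with the byte offset of the first error
#'
#' @param path Path to a JSON file.
#' @return Parsed JSON (lists preserved, no vector simplification).
#' @keywords internal
read_json_strict <- function(path) {
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  ok <- jsonlite::validate(txt)
  if (!isTRUE(ok)) {
    off <- attr(ok, "offset")
    stop(sprintf(
      "malformed JSON in '%s' at byte offset %s: %s",
      path, if (is.null(off)) "?" else off, attr(ok, "err")
    ), call. = FALSE)
  }
  jsonlite::fromJSON(txt, simplifyVector = FALSE)
}

#' Load a registry from structure and answers documents
#'
#' The structure document lists forms (with a repeatability flag) and their
#' questions with data types; the answers document lists, per patient, form
#' instances whose answer cells look like `"Q10": {"value": 63, "state":
#' "done"}`.  A `null` (or absent) value is a missing answer and is kept
#' distinct from the empty string.
#'
#' @param structure A path to a structure JSON file, or an equivalent
#'   already-parsed list with a `forms` element.
#' @param answers A path to an answers JSON file, or an equivalent list with
#'   a `patients` element.
#' @return A `registry` object: a list with tibbles `forms` (`form_id`,
#'   `repeatable`), `questions` (`qid`, `dtype`, `form_id`), `instances`
#'   (`patient_id`, `form_id`, `instance_index`) and `answers` (long table of
#'   answer cells with a list-column `value` and a character `state`).
#' @examples
#' reg <- generate_registry(synth_config(n_patients = 4, seed = 1))
#' reg$forms
#' @export
load_registry <- function(structure, answers) {
  sdoc <- if (is.character(structure)) read_json_strict(structure) else structure
  adoc <- if (is.character(answers)) read_json_strict(answers) else answers
  if (is.null(sdoc$forms)) stop("structure document has no 'forms' element")

  forms <- purrr::map_dfr(sdoc$forms, function(f) {
    tibble::tibble(form_id = f$form_id, repeatable = isTRUE(f$repeatable))
  })
  questions <- purrr::map_dfr(sdoc$forms, function(f) {
    purrr::map_dfr(f$questions, function(q) {
      if (!q$dtype %in% REGISTRY_DTYPES) {
        stop(sprintf("question '%s': unknown dtype '%s'", q$qid, q$dtype))
      }
      tibble::tibble(qid = q$qid, dtype = q$dtype, form_id = f$form_id)
    })
  })
  if (anyDuplicated(forms$form_id)) stop("duplicate form_id in structure")
  if (nrow(questions) && anyDuplicated(questions$qid)) {
    stop("duplicate qid in structure: ",
         paste(unique(questions$qid[duplicated(questions$qid)]), collapse = ", "))
  }

  inst <- list(); ans <- list()
  for (p in (adoc$patients %||% list())) {
    for (fi in (p$forms %||% list())) {
      idx <- as.integer(fi$instance_index %||% 1L)
      inst[[length(inst) + 1L]] <- tibble::tibble(
        patient_id = p$patient_id, form_id = fi$form_id, instance_index = idx
      )
      for (qid in names(fi$answers %||% list())) {
        if (!qid %in% questions$qid) {
          stop(sprintf("answer references unknown qid '%s' (patient %s)",
                       qid, p$patient_id), call. = FALSE)
        }
        if (questions$form_id[match(qid, questions$qid)] != fi$form_id) {
          stop(sprintf("qid '%s' answered under form '%s' it does not belong to",
                       qid, fi$form_id), call. = FALSE)
        }
        cell <- fi$answers[[qid]]
        ans[[length(ans) + 1L]] <- tibble::tibble(
          patient_id = p$patient_id, form_id = fi$form_id,
          instance_index = idx, qid = qid,
          value = list(cell$value), state = cell$state %||% NA_character_
        )
      }
    }
  }
  empty_inst <- tibble::tibble(patient_id = character(), form_id = character(),
                               instance_index = integer())
  empty_ans <- tibble::tibble(patient_id = character(), form_id = character(),
                              instance_index = integer(), qid = character(),
                              value = list(), state = character())
  structure(
    list(
      forms = forms, questions = questions,
      instances = if (length(inst)) dplyr::bind_rows(inst) else empty_inst,
      answers = if (length(ans)) dplyr::bind_rows(ans) else empty_ans
    ),
    class = "registry"
  )
}

#' @export
print.registry <- function(x, ...) {
  cat(sprintf(
    "<registry> %d form(s) (%d repeatable), %d question(s), %d patient(s), %d form instance(s)\n",
    nrow(x$forms), sum(x$forms$repeatable), nrow(x$questions),
    dplyr::n_distinct(x$instances$patient_id), nrow(x$instances)
  ))
  invisible(x)
}

#' Serialize a registry back to structure + answers JSON
#'
#' Inverse of [load_registry()]: writing then re-loading preserves values,
#' states and missingness.
#'
#' @param reg A `registry`.
#' @param structure_path,answers_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_registry <- function(reg, structure_path, answers_path) {
  forms <- purrr::pmap(reg$forms, function(form_id, repeatable) {
    qs <- dplyr::filter(reg$questions, .data$form_id == !!form_id)
    list(form_id = form_id, repeatable = repeatable,
         questions = purrr::pmap(qs[, c("qid", "dtype")], function(qid, dtype) {
           list(qid = qid, dtype = dtype)
         }))
  })
  patients <- lapply(split(reg$instances, reg$instances$patient_id), function(pi) {
    list(patient_id = pi$patient_id[[1L]],
         forms = purrr::pmap(pi, function(patient_id, form_id, instance_index) {
           a <- dplyr::filter(reg$answers,
                              .data$patient_id == !!patient_id,
                              .data$form_id == !!form_id,
                              .data$instance_index == !!instance_index)
           cells <- purrr::map2(a$value, a$state, function(v, s) {
             list(value = v, state = s)
           })
           names(cells) <- a$qid
           list(form_id = form_id, instance_index = instance_index,
                answers = cells)
         }))
  })
  names(patients) <- NULL
  jsonlite::write_json(list(forms = forms), structure_path,
                       auto_unbox = TRUE, null = "null", digits = NA)
  jsonlite::write_json(list(patients = patients), answers_path,
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(c(structure_path, answers_path))
}

# ---- flat tables -----------------------------------------------------------

#' Construct a flat table
#'
#' A flat table is a tibble with key columns `patient_id` and
#' `instance_index` followed by one column per question, carrying its
#' question data types, kind (`"prefix"` or `"semiflattened"`) and, for
#' semi-flattened tables, the repeating form id as attributes.
#'
#' @param data Tibble with `patient_id`, `instance_index` and qid columns.
#' @param dtypes Named character vector mapping qid to dtype.
#' @param kind `"prefix"` or `"semiflattened"`.
#' @param form_id Repeating form id for semi-flattened tables.
#' @return A `flat_table`.
#' @export
new_flat_table <- function(data, dtypes, kind = c("prefix", "semiflattened"),
                           form_id = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(c("patient_id", "instance_index") %in% names(data)))
  qids <- setdiff(names(data), c("patient_id", "instance_index"))
  if (!all(qids %in% names(dtypes))) {
    stop("dtypes missing for: ", paste(setdiff(qids, names(dtypes)), collapse = ", "))
  }
  structure(
    tibble::as_tibble(data),
    aqc_dtypes = dtypes[qids], aqc_kind = kind, aqc_form = form_id,
    class = c("flat_table", class(tibble::tibble()))
  )
}

#' @rdname new_flat_table
#' @param t A `flat_table`.
#' @export
ft_dtypes <- function(t) attr(t, "aqc_dtypes")

#' @rdname new_flat_table
#' @export
ft_qids <- function(t) setdiff(names(t), c("patient_id", "instance_index"))

#' @rdname new_flat_table
#' @export
ft_kind <- function(t) attr(t, "aqc_kind")

na_of <- function(dtype) {
  switch(dtype,
    integer = NA_integer_, float = NA_real_, boolean = NA,
    NA_character_
  )
}

cast_cell <- function(v, dtype) {
  if (is.null(v)) return(na_of(dtype))
  switch(dtype,
    integer = as.integer(v),
    float = as.numeric(v),
    boolean = as.logical(v),
    as.character(v)
  )
}

# Build typed qid columns for a set of (patient_id, instance_index) row keys
# from the long answers table of one or more forms.
fill_columns <- function(reg, row_keys, qids) {
  qinfo <- reg$questions[match(qids, reg$questions$qid), ]
  key <- paste(row_keys$patient_id, row_keys$instance_index, sep = "\r")
  cols <- purrr::map2(qinfo$qid, qinfo$dtype, function(qid, dtype) {
    col <- rep(na_of(dtype), nrow(row_keys))
    a <- reg$answers[reg$answers$qid == qid, ]
    if (nrow(a)) {
      akey <- paste(a$patient_id, a$instance_index, sep = "\r")
      hit <- match(akey, key)
      keep <- !is.na(hit)
      if (any(keep)) {
        col[hit[keep]] <- unlist(lapply(a$value[keep], cast_cell,
                                        dtype = dtype))
      }
    }
    col
  })
  names(cols) <- qinfo$qid
  tibble::as_tibble(cols)
}

#' Build the prefix table of a registry
#'
#' Serializes all non-repeatable forms into one wide row per patient.
#' Unanswered questions are materialized as missing cells so the column set
#' is identical across rows.
#'
#' @param reg A `registry`.
#' @return A `flat_table` of kind `"prefix"` (one row per patient,
#'   `instance_index` is `NA`).
#' @export
build_prefix_table <- function(reg) {
  single <- reg$forms$form_id[!reg$forms$repeatable]
  dup <- reg$instances |>
    dplyr::filter(.data$form_id %in% single) |>
    dplyr::count(.data$patient_id, .data$form_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop(sprintf(
      "non-repeatable form '%s' has %d instances for patient '%s'",
      dup$form_id[[1L]], dup$n[[1L]], dup$patient_id[[1L]]
    ), call. = FALSE)
  }
  patients <- sort(unique(reg$instances$patient_id))
  qids <- reg$questions$qid[reg$questions$form_id %in% single]
  row_keys <- tibble::tibble(patient_id = patients, instance_index = NA_integer_)
  # prefix answers live on instance_index 1; match on that key
  lookup_keys <- tibble::tibble(patient_id = patients, instance_index = 1L)
  cols <- fill_columns(reg, lookup_keys, qids)
  new_flat_table(
    dplyr::bind_cols(row_keys, cols),
    dtypes = stats::setNames(
      reg$questions$dtype[match(qids, reg$questions$qid)], qids
    ),
    kind = "prefix"
  )
}

#' Build all semi-flattened tables of a registry
#'
#' One table per repeatable form: each row joins a patient's prefix cells to
#' one instance of that form, so every column holds a single well-defined
#' variable.  Patients with no instance of the form contribute no row.
#'
#' @param reg A `registry`.
#' @return Named list of `flat_table`s of kind `"semiflattened"`, one per
#'   repeatable form (empty list if the registry has none).
#' @export
build_semiflattened_tables <- function(reg) {
  prefix <- build_prefix_table(reg)
  rep_forms <- reg$forms$form_id[reg$forms$repeatable]
  out <- lapply(rep_forms, function(fid) {
    inst <- reg$instances |>
      dplyr::filter(.data$form_id == fid) |>
      dplyr::arrange(.data$patient_id, .data$instance_index)
    qids <- reg$questions$qid[reg$questions$form_id == fid]
    row_keys <- tibble::tibble(patient_id = inst$patient_id,
                               instance_index = inst$instance_index)
    form_cols <- fill_columns(reg, row_keys, qids)
    prefix_cells <- prefix[match(inst$patient_id, prefix$patient_id),
                           ft_qids(prefix), drop = FALSE]
    new_flat_table(
      dplyr::bind_cols(row_keys, tibble::as_tibble(prefix_cells), form_cols),
      dtypes = c(ft_dtypes(prefix), stats::setNames(
        reg$questions$dtype[match(qids, reg$questions$qid)], qids
      )),
      kind = "semiflattened", form_id = fid
    )
  })
  names(out) <- rep_forms
  out
}

#' Number of detection runs a registry requires
#'
#' The detection pipeline runs once on the prefix table and once per
#' repeatable form's semi-flattened table, i.e. `n_semiflattened + 1` times.
#'
#' @param reg A `registry`.
#' @return Integer count of runs.
#' @export
n_detection_runs <- function(reg) sum(reg$forms$repeatable) + 1L

#' Read / write a flat table as CSV
#'
#' Header row of qids, empty field = missing, RFC 4180 quoting.  Data types
#' are passed alongside because CSV does not carry them.
#'
#' @param path CSV file path.
#' @param dtypes Named character vector qid -> dtype for the non-key columns.
#' @param kind,form_id See [new_flat_table()].
#' @return A `flat_table` (for the reader); invisibly `path` (writer).
#' @export
read_flat_csv <- function(path, dtypes, kind = "prefix", form_id = NULL) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         na.strings = character())
  if (!"patient_id" %in% names(raw)) stop("CSV lacks a patient_id column")
  if (!"instance_index" %in% names(raw)) raw$instance_index <- NA_integer_
  raw$instance_index <- suppressWarnings(as.integer(raw$instance_index))
  qids <- setdiff(names(raw), c("patient_id", "instance_index"))
  for (q in qids) {
    col <- raw[[q]]
    col[col == ""] <- NA
    raw[[q]] <- switch(dtypes[[q]],
      integer = as.integer(col), float = as.numeric(col),
      boolean = as.logical(col), col
    )
  }
  new_flat_table(tibble::as_tibble(raw), dtypes = dtypes, kind = kind,
                 form_id = form_id)
}

#' @rdname read_flat_csv
#' @param t A `flat_table`.
#' @export
write_flat_csv <- function(t, path) {
  out <- as.data.frame(t)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
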