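# Fixtures built in code: a small registry with two single-instance forms
# (Subject, Hospitalization) and two repeating forms (Follow-up, Quality of
# Life), mirroring the canonical prefix/semi-flattened layout.

fix_structure <- function() {
  list(forms = list(
    list(form_id = "subject", repeatable = FALSE, questions = list(
      list(qid = "A0.P0.F1.G1.Q1", dtype = "integer"),
      list(qid = "A0.P0.F1.G1.Q2", dtype = "categorical"),
      list(qid = "A0.P0.F1.G1.Q3", dtype = "date"),
      list(qid = "A0.P0.F1.G1.Q4", dtype = "text")
    )),
    list(form_id = "hospitalization", repeatable = FALSE, questions = list(
      list(qid = "A0.P0.F2.G1.Q1", dtype = "float"),
      list(qid = "A0.P0.F2.G1.Q2", dtype = "boolean")
    )),
    list(form_id = "followup", repeatable = TRUE, questions = list(
      list(qid = "A0.P1.F3.G1.Q1", dtype = "float"),
      list(qid = "A0.P1.F3.G1.Q2", dtype = "categorical")
    )),
    list(form_id = "qol", repeatable = TRUE, questions = list(
      list(qid = "A0.P2.F4.G1.Q1", dtype = "integer")
    ))
  ))
}

cell <- function(value, state = "done") list(value = value, state = state)

fix_answers <- function() {
  list(patients = list(
    list(patient_id = "P-A", forms = list(
      list(form_id = "subject", instance_index = 1, answers = list(
        "A0.P0.F1.G1.Q1" = cell(63),
        "A0.P0.F1.G1.Q2" = cell("Female"),
        "A0.P0.F1.G1.Q3" = cell("1947-01-23"),
        "A0.P0.F1.G1.Q4" = cell("free text note")
      )),
      list(form_id = "hospitalization", instance_index = 1, answers = list(
        "A0.P0.F2.G1.Q1" = cell(7.5),
        "A0.P0.F2.G1.Q2" = cell(TRUE)
      )),
      list(form_id = "followup", instance_index = 1, answers = list(
        "A0.P1.F3.G1.Q1" = cell(64.2),
        "A0.P1.F3.G1.Q2" = cell("stable")
      )),
      list(form_id = "followup", instance_index = 2, answers = list(
        "A0.P1.F3.G1.Q1" = cell(66.0),
        "A0.P1.F3.G1.Q2" = cell("improved")
      ))
    )),
    list(patient_id = "P-B", forms = list(
      list(form_id = "subject", instance_index = 1, answers = list(
        "A0.P0.F1.G1.Q1" = cell(58),
        "A0.P0.F1.G1.Q2" = cell("Male"),
        "A0.P0.F1.G1.Q3" = cell(NULL, state = "missing"),
        "A0.P0.F1.G1.Q4" = cell("")
      )),
      list(form_id = "hospitalization", instance_index = 1, answers = list(
        "A0.P0.F2.G1.Q1" = cell(6.1),
        "A0.P0.F2.G1.Q2" = cell(FALSE)
      )),
      list(form_id = "followup", instance_index = 1, answers = list(
        "A0.P1.F3.G1.Q1" = cell(60.4),
        "A0.P1.F3.G1.Q2" = cell("stable")
      )),
      list(form_id = "followup", instance_index = 2, answers = list(
        "A0.P1.F3.G1.Q1" = cell(61.0),
        "A0.P1.F3.G1.Q2" = cell("stable")
      )),
      list(form_id = "followup", instance_index = 3, answers = list(
        "A0.P1.F3.G1.Q1" = cell(62.7),
        "A0.P1.F3.G1.Q2" = cell("worse")
      )),
      list(form_id = "qol", instance_index = 1, answers = list(
        "A0.P2.F4.G1.Q1" = cell(80)
      ))
    ))
  ))
}

fix_registry <- function() load_registry(fix_structure(), fix_answers())

# Minimal numeric flat table with explicit dtypes.
fix_numeric_table <- function(cols, dtypes = NULL) {
  n <- length(cols[[1L]])
  if (is.null(dtypes)) {
    dtypes <- stats::setNames(rep("float", length(cols)), names(cols))
  }
  new_flat_table(
    dplyr::bind_cols(
      tibble::tibble(patient_id = sprintf("S%03d", seq_len(n)),
                     instance_index = NA_integer_),
      tibble::as_tibble(cols)
    ),
    dtypes = dtypes, kind = "prefix"
  )
}

# Brute-force oracle: naive distances + thresholds + union rule, written
# independently of the pipeline internals.
oracle_anomalies <- function(values, metrics, percentiles, mink_p = 3,
                             mah_ridge = 1e-6) {
  ctr <- apply(values, 2, mean)
  n <- nrow(values)
  inv <- NULL
  if ("MAH" %in% metrics) {
    inv <- solve(cov(values) + diag(mah_ridge, ncol(values)))
  }
  flagged <- rep(FALSE, n)
  strength <- rep(0L, n)
  for (k in metrics) {
    d <- numeric(n)
    for (i in seq_len(n)) {
      x <- values[i, ]; dd <- x - ctr
      d[[i]] <- switch(k,
        CAN = { den <- abs(x) + abs(ctr); sum(ifelse(den == 0, 0, abs(dd) / den)) },
        CHEB = max(abs(dd)),
        COS = {
          nx <- sqrt(sum(x^2)); nc <- sqrt(sum(ctr^2))
          if (nx == 0 || nc == 0) 1 else 1 - sum(x * ctr) / (nx * nc)
        },
        EUC = sqrt(sum(dd^2)),
        MAN = sum(abs(dd)),
        MAH = sqrt(sum((dd %*% inv) * dd)),
        MINK = sum(abs(dd)^mink_p)^(1 / mink_p)
      )
    }
    q <- quantile(d, c(0.25, 0.75, percentiles[[k]] / 100), type = 7,
                  names = FALSE)
    thr <- min(q[[3L]], q[[2L]] + 1.5 * (q[[2L]] - q[[1L]]))
    hit <- d > thr
    flagged <- flagged | hit
    strength <- strength + hit
  }
  list(anomalous = which(flagged), strength = strength)
}
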