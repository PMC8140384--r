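test_that("metric distances reproduce hand arithmetic and standard identities", {
  x <- c(0, 0); y <- c(3, 4)
  expect_equal(metric_distance(x, y, "EUC"), 5)
  expect_equal(metric_distance(x, y, "MAN"), 7)
  expect_equal(metric_distance(x, y, "CHEB"), 4)
  expect_equal(metric_distance(x, y, "CAN"), 2)  # 0/0 terms count as 0
  expect_equal(metric_distance(x, y, "MINK", p = 3), 91^(1 / 3))
  expect_equal(metric_distance(c(1, 0), c(0, 1), "COS"), 1)
  expect_equal(metric_distance(c(0, 0), c(1, 1), "COS"), 1)  # zero norm

  # scipy-checked reference pair (values pinned from an external run)
  a <- c(0.1, 0.4, 0.9, 0.3); b <- c(0.2, 0.2, 0.5, 0.8)
  expect_equal(metric_distance(a, b, "CAN"), 1.406926406926407, tolerance = 1e-12)
  expect_equal(metric_distance(a, b, "COS"), 0.22455797239066988, tolerance = 1e-12)
  expect_equal(metric_distance(a, b, "MINK", p = 3), 0.5828476683251457,
               tolerance = 1e-12)

  set.seed(1)
  for (i in 1:5) {
    u <- runif(6); v <- runif(6)
    # identity of indiscernibles and symmetry for all seven metrics
    eye <- diag(6)
    for (k in METRIC_KINDS) {
      expect_equal(metric_distance(u, u, k, inv_cov = eye), 0)
      expect_equal(metric_distance(u, v, k, inv_cov = eye),
                   metric_distance(v, u, k, inv_cov = eye))
    }
    # MINK(1) = MAN, MINK(2) = EUC, MAH(I) = EUC
    expect_equal(metric_distance(u, v, "MINK", p = 1),
                 metric_distance(u, v, "MAN"), tolerance = 1e-9)
    expect_equal(metric_distance(u, v, "MINK", p = 2),
                 metric_distance(u, v, "EUC"), tolerance = 1e-9)
    expect_equal(metric_distance(u, v, "MAH", inv_cov = eye),
                 metric_distance(u, v, "EUC"), tolerance = 1e-9)
    # CHEB <= MINK(64) <= CHEB * dim^(1/64); CAN <= dim
    m64 <- metric_distance(u, v, "MINK", p = 64)
    expect_gte(m64, metric_distance(u, v, "CHEB"))
    expect_lte(m64, metric_distance(u, v, "CHEB") * 6^(1 / 64) + 1e-12)
    expect_lte(metric_distance(u, v, "CAN"), 6)
  }
  expect_error(metric_distance(c(1, 2), c(1, 2, 3), "EUC"), "dimension")
  expect_error(metric_distance(c(1, NA), c(1, 2), "EUC"), "non-finite")
})

test_that("centroid is the column mean and matches a summation oracle", {
  expect_equal(centroid(rbind(c(0, 0), c(1, 1))), c(0.5, 0.5))
  expect_equal(centroid(matrix(c(0.3, 0.7), nrow = 1)), c(0.3, 0.7))
  set.seed(3)
  m <- matrix(runif(400), 100, 4)
  oracle <- vapply(1:4, function(j) sum(m[, j]) / 100, numeric(1))
  expect_equal(centroid(m), oracle, tolerance = 1e-12)
  expect_error(centroid(matrix(numeric(), 0, 3)), "at least one row")
})

test_that("Mahalanobis parameters recover identity covariance and tolerate degeneracy", {
  set.seed(8)
  m <- matrix(rnorm(2000 * 2), ncol = 2)
  inv <- mahalanobis_params(m, ridge = 0)
  expect_equal(unclass(inv), diag(2), tolerance = 0.1, ignore_attr = TRUE)
  expect_equal(attr(inv, "method"), "solve")

  # constant column: finite result, no crash
  mc <- cbind(rnorm(50), rep(1, 50))
  invc <- mahalanobis_params(mc)
  expect_true(all(is.finite(invc)))

  # ridge stability on well-conditioned data
  set.seed(9)
  mw <- matrix(10 * runif(300), ncol = 3)
  ctr <- centroid(mw)
  d1 <- apply(mw, 1, metric_distance, y = ctr, kind = "MAH",
              inv_cov = mahalanobis_params(mw, 1e-6))
  d2 <- apply(mw, 1, metric_distance, y = ctr, kind = "MAH",
              inv_cov = mahalanobis_params(mw, 1e-3))
  expect_equal(d1, d2, tolerance = 1e-3)
  expect_error(mahalanobis_params(matrix(1, 1, 3)), "at least 2 rows")

  # cross-check against stats::mahalanobis
  dd <- sqrt(stats::mahalanobis(mw, ctr, cov(mw) + diag(1e-6, 3)))
  expect_equal(d1, dd, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("thresholds take the minimum of interpolated percentile and Tukey fence", {
  thr <- compute_thresholds(1:100, 95, metric = "MAN")
  expect_equal(thr$percentile_threshold, 95.05)
  expect_equal(thr$iqr_threshold, 149.5)
  expect_equal(thr$effective_threshold, 95.05)

  # all-equal distances: both thresholds c, nothing exceeds (strict >)
  thr2 <- compute_thresholds(rep(3, 20), 90)
  expect_equal(thr2$effective_threshold, 3)
  expect_false(any(rep(3, 20) > thr2$effective_threshold))

  # one extreme value: the IQR fence undercuts the extreme, which exceeds
  set.seed(4)
  d <- c(runif(99), 10)
  thr3 <- compute_thresholds(d, 95)
  expect_lt(thr3$iqr_threshold, 10)
  expect_true(10 > thr3$effective_threshold)
  expect_error(compute_thresholds(numeric(), 95), "empty")
})

test_that("detection applies the union rule with strength counting", {
  # 10 identical rows -> all distances zero, nothing anomalous
  pm0 <- preprocess(fix_numeric_table(
    list(a = rep(5, 10), b = rep(2, 10)),
    dtypes = c(a = "float", b = "float")
  ))
  det0 <- detect_anomalies(pm0, metrics = c("MAN", "CAN"))
  expect_false(any(det0$rows$anomalous))
  expect_true(all(det0$rows$strength == 0L))

  # 99 tight rows + 1 row shifted 6 sigma in two coordinates
  set.seed(10)
  a <- rnorm(99, 0.5, 0.02); b <- rnorm(99, 0.5, 0.02)
  t <- fix_numeric_table(list(a = c(a, 0.5 + 6 * 0.02 * 10),
                              b = c(b, 0.5 - 6 * 0.02 * 10)),
                         dtypes = c(a = "float", b = "float"))
  det <- detect_anomalies(preprocess(t), metrics = c("MAN", "CAN"),
                          percentiles = c(MAN = 95, CAN = 95))
  expect_true(det$rows$anomalous[[100L]])
  expect_equal(det$rows$strength[[100L]], 2L)
  expect_equal(det$rows$anomalous, det$rows$strength >= 1L)

  # union monotonicity: anomalies({MAN}) subset of anomalies({MAN, CAN})
  reg <- generate_registry(synth_config(n_patients = 60, seed = 21))
  pm <- preprocess(build_prefix_table(reg))
  one <- which(detect_anomalies(pm, metrics = "MAN")$rows$anomalous)
  two <- which(detect_anomalies(pm, metrics = c("MAN", "CAN"))$rows$anomalous)
  expect_true(all(one %in% two))

  # metric without a configured percentile -> config error
  expect_error(detect_anomalies(pm, metrics = "MAN", percentiles = c(CAN = 90)),
               "MAN")
})

test_that("raising the percentile never grows a single metric's flagged set", {
  set.seed(11)
  pm <- preprocess(generate_clean_matrix(120, 6, seed = 11))
  flagged <- lapply(c(70, 80, 90, 95), function(p) {
    which(detect_anomalies(pm, metrics = "EUC",
                           percentiles = c(EUC = p))$rows$anomalous)
  })
  for (i in 1:3) expect_true(all(flagged[[i + 1L]] %in% flagged[[i]]))
})

test_that("pipeline anomaly sets equal a naive brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    vals <- matrix(runif(80), 20, 4)
    t <- fix_numeric_table(stats::setNames(
      as.list(as.data.frame(vals)), paste0("q", 1:4)
    ))
    pm <- preprocess(t)
    mets <- c("CAN", "EUC", "MAH", "MAN", "MINK")
    pct <- default_percentiles()[mets]
    det <- detect_anomalies(pm, metrics = mets, percentiles = pct)
    oracle <- oracle_anomalies(pm$values, mets, pct)
    expect_equal(which(det$rows$anomalous), oracle$anomalous)
    expect_equal(det$rows$strength, oracle$strength)
  }
})

test_that("post-hoc tests flag deviating variables per distribution branch", {
  set.seed(12)
  n <- 120
  gauss <- rnorm(n - 1, 0.5, 0.01)
  skew <- rlnorm(n - 1, 0, 0.5)
  t <- fix_numeric_table(list(
    gauss = c(gauss, 0.99),          # z approx 49 -> flagged
    skew = c(skew, stats::median(skew))  # inside the fences -> not flagged
  ))
  pm <- preprocess(t)
  flags <- posthoc_flag_variables(pm, n)
  expect_true("gauss" %in% flags)
  expect_false("skew" %in% flags)

  # a row at the centroid flags nothing
  ctr_t <- fix_numeric_table(list(a = c(rnorm(50, 0.5, 0.1), 0.5)))
  pmc <- preprocess(ctr_t)
  pmc$values[51L, ] <- centroid(pmc)
  expect_length(posthoc_flag_variables(pmc, 51L), 0L)
  expect_error(posthoc_flag_variables(pm, 9999L), "unknown row_key")
})

test_that("queries aggregate per patient with max strength and union of variables", {
  mk_det <- function(pids, strengths, metrics = c("MAN", "CAN")) {
    structure(list(
      rows = tibble::tibble(
        patient_id = pids, instance_index = NA_integer_,
        strength = as.integer(strengths), anomalous = strengths >= 1L
      ),
      metrics = metrics
    ), class = "detection_result")
  }
  # same patient anomalous in 2 runs with strengths 1 and 2 -> one record, strength 2
  q <- generate_queries(
    list(mk_det(c("P1", "P2"), c(1L, 0L)), mk_det("P1", 2L)),
    flags = list(P1 = "qA", P1 = "qB")
  )
  expect_equal(nrow(q), 1L)
  expect_equal(q$strength, 2L)
  expect_equal(q$flagged_variables[[1L]], c("qA", "qB"))

  # ordering: strength desc, then patient id asc
  q2 <- generate_queries(mk_det(c("PZ", "PA", "PB"), c(1L, 1L, 3L)))
  expect_equal(q2$patient_id, c("PB", "PA", "PZ"))

  # no anomalies -> empty tibble and empty JSONL file
  q0 <- generate_queries(mk_det("P1", 0L))
  expect_equal(nrow(q0), 0L)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_queries_jsonl(q0, f)
  expect_length(readLines(f), 0L)
  write_queries_jsonl(q, f)
  rec <- jsonlite::fromJSON(readLines(f)[[1L]])
  expect_equal(rec$patient_id, "P1")
  expect_equal(rec$flagged_variables, c("qA", "qB"))
})
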