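test_that("confusion matrices follow set algebra and conserve row counts", {
  expect_equal(confusion(c(3, 7), c(3, 7), 10),
               tibble::tibble(TP = 2L, FP = 0L, TN = 8L, FN = 0L))
  # null detector on a 29-row cohort with 7 true anomalies
  expect_equal(confusion(integer(), 1:7, 29),
               tibble::tibble(TP = 0L, FP = 0L, TN = 22L, FN = 7L))
  # random predictor vs a brute-force tally
  set.seed(20)
  for (i in 1:5) {
    n <- 50L
    truth <- sample.int(n, 8)
    pred <- sample.int(n, 25)
    cm <- confusion(pred, truth, n)
    tp <- sum(pred %in% truth)
    expect_equal(cm$TP, tp)
    expect_equal(cm$FP, 25L - tp)
    expect_equal(cm$FN, 8L - tp)
    expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, n)
  }
  expect_error(confusion(1:3, c(1, 99), 50), "outside")
})

test_that("performance measures reproduce published-table arithmetic", {
  # sens/spec pairs from single-metric classifier rows; Youden and ULC_dist
  # follow to +-0.001
  rows <- list(
    list(sens = 0.8182, spec = 0.8094, youden = 0.628, ulc = 0.263),
    list(sens = 0.8182, spec = 0.8721, youden = 0.690, ulc = 0.222),
    list(sens = 0.8182, spec = 0.8982, youden = 0.716, ulc = 0.208),
    list(sens = 0.5714, spec = 0.8636, youden = 0.435, ulc = 0.450),
    list(sens = 0.6364, spec = 0.9086, youden = 0.545, ulc = 0.375)
  )
  for (r in rows) {
    cm <- reconstruct_confusion(r$sens, r$spec, n_pos = 100000, n_neg = 100000)
    perf <- perf_metrics(cm)
    expect_lt(abs(perf$youden - r$youden), 0.001)
    expect_lt(abs(perf$ulc_dist - r$ulc), 0.001)
  }
  # perfect corner
  perfect <- perf_metrics(tibble::tibble(TP = 5, FP = 0, TN = 5, FN = 0))
  expect_equal(perfect$youden, 1)
  expect_equal(perfect$ulc_dist, 0)
  expect_equal(perfect$balanced_accuracy, 1)
  # zero-denominator convention
  degen <- perf_metrics(tibble::tibble(TP = 0, FP = 0, TN = 10, FN = 0))
  expect_equal(degen$sensitivity, 0)
  expect_equal(degen$precision, 0)
})

test_that("C2 is balanced accuracy plus sensitivity", {
  expect_equal(round(c2_criterion(0.9546, 0.7937), 3), 1.829)
  expect_equal(round(c2_criterion(0.8571, 0.6818), 3), 1.627)
  expect_equal(c2_criterion(1, 1), 2)
  # algebraic identity against perf_metrics on random confusion matrices
  set.seed(21)
  for (i in 1:10) {
    cm <- tibble::tibble(TP = sample(0:20, 1), FP = sample(0:20, 1),
                         TN = sample(1:50, 1), FN = sample(0:20, 1))
    p <- perf_metrics(cm)
    expect_equal(c2_criterion(p$sensitivity, p$specificity),
                 p$balanced_accuracy + p$sensitivity)
  }
})

test_that("C1 normalizes members across the candidate list", {
  one <- tibble::tibble(accuracy = 0.9, youden = 0.5, ulc_dist = 0.3)
  expect_equal(c1_criterion(one), 0)  # constant members -> 0
  two <- tibble::tibble(accuracy = c(0.5, 0.9), youden = c(0.2, 0.8),
                        ulc_dist = c(0.6, 0.1))
  expect_equal(c1_criterion(two), c(-1, 2))  # corner normalization
  # 81-candidate list: argmax agrees with an independent re-computation
  set.seed(22)
  cand <- tibble::tibble(accuracy = runif(81), youden = runif(81, -1, 1),
                         ulc_dist = runif(81, 0, 1.4))
  c1 <- c1_criterion(cand)
  nrm <- function(x) (x - min(x)) / (max(x) - min(x))
  oracle <- nrm(cand$accuracy)^2 + nrm(cand$youden)^2 - nrm(cand$ulc_dist)^2
  expect_equal(which.max(c1), which.max(oracle))
  expect_equal(c1, oracle)
})

test_that("ROC scan picks the C1-best percentile and yields valid curves", {
  expect_length(roc_grid(), 81L)
  expect_equal(range(roc_grid()), c(5, 95))

  # separable fixture: anomaly distances strictly above the 96th percentile
  set.seed(23)
  d <- c(runif(96, 0, 1), runif(4, 5, 6))
  distances <- matrix(d, ncol = 1, dimnames = list(NULL, "EUC"))
  scan <- roc_scan(distances, truth = 97:100)
  best <- scan$best_points
  expect_lte(best$percentile, 95)
  expect_equal(best$tpr, 1)

  # degenerate truth: every row anomalous; no crash, fpr identically 0
  scan_all <- roc_scan(distances, truth = 1:100)
  expect_true(all(scan_all$curves$fpr == 0))

  # validity and monotonicity over the grid for every metric
  set.seed(24)
  dm <- cbind(EUC = rexp(200), MAN = rexp(200))
  truth <- sample.int(200, 20)
  scan2 <- roc_scan(dm, truth)
  expect_true(all(scan2$curves$tpr >= 0 & scan2$curves$tpr <= 1))
  expect_true(all(scan2$curves$fpr >= 0 & scan2$curves$fpr <= 1))
  by_metric <- split(scan2$curves, scan2$curves$metric)
  for (cur in by_metric) {
    cur <- cur[order(cur$percentile), ]
    expect_true(all(diff(cur$tpr) <= 1e-12))
    expect_true(all(diff(cur$fpr) <= 1e-12))
  }
  expect_error(roc_scan(dm, truth, grid = numeric()), "empty")
})

test_that("ensemble search ranks all non-empty subsets under the union rule", {
  set.seed(25)
  n <- 60L
  flags <- cbind(
    CAN = runif(n) < 0.2, EUC = runif(n) < 0.15, MAH = runif(n) < 0.1,
    MAN = runif(n) < 0.15, MINK = runif(n) < 0.12
  )
  truth <- sample.int(n, 8)
  res <- ensemble_search(flags, truth)
  expect_equal(nrow(res), 31L)  # 2^5 - 1
  expect_equal(res$c2, res$balanced_accuracy + res$sensitivity)
  expect_true(all(diff(res$c2) <= 1e-12))  # sorted descending

  # union-rule dominance: supersets never lose sensitivity nor gain specificity
  lookup <- function(s) res[res$combination == paste(sort(s), collapse = "+"), ]
  for (i in 1:10) {
    small <- sample(colnames(flags), 2)
    big <- c(small, sample(setdiff(colnames(flags), small), 1))
    expect_gte(lookup(big)$sensitivity, lookup(small)$sensitivity)
    expect_lte(lookup(big)$specificity, lookup(small)$specificity)
    # each member's sensitivity never exceeds the subset's
    for (k in small) expect_gte(lookup(small)$sensitivity, lookup(k)$sensitivity)
  }
  expect_error(ensemble_search(flags, truth, pool = character()), "empty")
})

test_that("reconstructed confusion counts reproduce printed accuracy and precision", {
  # 29-row validation cohort, 7 anomalies: sens 85.71 / spec 72.73
  cm <- reconstruct_confusion(0.8571, 0.7273, n_pos = 7, n_neg = 22)
  expect_equal(unlist(cm), c(TP = 6, FP = 6, TN = 16, FN = 1))
  p <- perf_metrics(cm)
  expect_equal(round(100 * p$accuracy, 2), 75.86)
  expect_equal(round(100 * p$precision, 2), 50.00)

  # 405-row evaluation cohort, 22 anomalies: sens 95.46 / spec 79.37
  cm2 <- reconstruct_confusion(0.9546, 0.7937, n_pos = 22, n_neg = 383)
  expect_equal(cm2$TP, 21)
  expect_equal(cm2$FP, 79)
  p2 <- perf_metrics(cm2)
  expect_equal(round(100 * p2$precision, 2), 21.00)
  expect_equal(round(100 * p2$error, 2), 19.75)
  expect_equal(round(100 * p2$balanced_accuracy, 2), 87.41)

  expect_equal(unlist(reconstruct_confusion(1, 1, 5, 9)),
               c(TP = 5, FP = 0, TN = 9, FN = 0))
})
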