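test_that("confusion metrics match the hand-built table and a counting oracle", {
  y <- c(0, 0, 1, 1); yhat <- c(0, 1, 1, 1)
  cm <- confusion_metrics(truth = y, estimate = yhat)
  expect_equal(cm$accuracy, 0.75)
  c1 <- cm$per_class[cm$per_class$class == 1, ]
  expect_equal(c1$precision, 2 / 3)
  expect_equal(c1$recall, 1)
  expect_equal(c1$f1, 0.8)
  expect_equal(cm$macro_f1, (2 / 3 + 0.8) / 2, tolerance = 1e-6)

  perfect <- confusion_metrics(truth = y, estimate = y)
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$macro_f1, 1)
  expect_equal(perfect$micro_f1, 1)

  # counting oracle over many random sequences; micro-F1 == accuracy
  set.seed(61)
  for (trial in 1:1000) {
    K <- sample(2:5, 1); Tn <- sample(5:30, 1)
    yy <- sample(0:(K - 1), Tn, replace = TRUE)
    hh <- sample(0:(K - 1), Tn, replace = TRUE)
    got <- confusion_metrics(truth = yy, estimate = hh, K = K)
    orc <- confusion_oracle(yy, hh, 0:(K - 1))
    expect_equal(got$accuracy, orc$accuracy)
    expect_equal(got$macro_f1, as.numeric(orc$macro_f1), tolerance = 1e-12)
    expect_equal(got$micro_f1, got$accuracy, tolerance = 1e-12)
  }
})

test_that("Cohen's kappa matches hand computations and stays in [-1, 1]", {
  y <- c(0, 0, 1, 1)
  expect_equal(cohens_kappa(truth = y, estimate = y), 1)
  expect_equal(cohens_kappa(truth = y, estimate = c(0, 1, 0, 1)), 0)
  expect_equal(cohens_kappa(truth = y, estimate = c(0, 0, 1, 0)), 0.5)
  set.seed(62)
  for (trial in 1:50) {
    yy <- sample(0:2, 20, replace = TRUE)
    hh <- sample(0:2, 20, replace = TRUE)
    k <- cohens_kappa(truth = yy, estimate = hh)
    expect_gte(k, -1); expect_lte(k, 1)
  }
  expect_warning(k1 <- cohens_kappa(truth = rep(0, 5), estimate = rep(0, 5)),
                 "expected agreement")
  expect_equal(k1, 1)
})

test_that("AUC-ROC equals the Mann-Whitney pair-counting oracle", {
  expect_equal(roc_pr_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc_roc, 1)
  expect_equal(roc_pr_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$auc_roc, 0)
  set.seed(63)
  for (trial in 1:200) {
    n <- sample(6:25, 1)
    truth <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)   # ties included
    got <- roc_pr_auc(scores, truth)$auc_roc
    expect_equal(got, auc_pair_count(scores, truth), tolerance = 1e-10)
  }
  expect_warning(out <- roc_pr_auc(rnorm(5), rep(1, 5)), "single-class")
  expect_true(is.na(out$auc_roc))
})

test_that("AUC-ROC agrees with an established implementation on random data", {
  skip_if_not_installed("pROC")
  set.seed(64)
  for (trial in 1:20) {
    truth <- c(0, 1, sample(0:1, 30, replace = TRUE))
    scores <- rnorm(32)
    ref <- suppressMessages(as.numeric(pROC::auc(truth, scores,
                                                 direction = "<", quiet = TRUE)))
    expect_equal(roc_pr_auc(scores, truth)$auc_roc, ref, tolerance = 1e-10)
  }
})

test_that("transition accuracy scores matched change indicators", {
  expect_equal(transition_accuracy(truth = c(1, 1, 1), estimate = c(2, 2, 2)), 1)
  expect_equal(transition_accuracy(truth = c(0, 0, 1), estimate = c(0, 1, 1)), 0)
  expect_equal(transition_accuracy(truth = c(0, 1, 1), estimate = c(2, 0, 0)), 1)
})

test_that("consistency score penalizes predicted transitions", {
  expect_equal(consistency_score(truth = c(0, 1, 2), estimate = c(1, 1, 1)), 1)
  expect_equal(consistency_score(truth = c(0, 0, 0), estimate = c(0, 1, 1)), 0.5)
  expect_equal(consistency_score(truth = c(0, 1, 0), estimate = c(0, 1, 2)), 0)
  om <- matrix(2, 3, 3)
  expect_equal(consistency_score(truth = c(0, 0, 0), estimate = c(0, 1, 1),
                                 omega = om), 0)
})

test_that("event IoU, matching, and detection delays follow the interval rules", {
  w <- tibble::tibble(start = seq(0, 135, 15), end = seq(30, 165, 15))
  truth <- c(0, 0, 1, 1, 1, 0, 0, 2, 2, 0)
  spans <- labels_to_spans(truth, w)
  expect_equal(nrow(spans), 2)
  expect_equal(spans$start, c(30, 105))
  expect_equal(spans$end, c(90, 150))

  # identical spans: IoU 1, delay 0
  wt <- tibble::tibble(time = (w$start + w$end) / 2, estimate = truth)
  em <- event_detection_metrics(spans, spans, 0.5, wt)
  expect_equal(em$event_f1, 1)
  expect_equal(em$matches$iou, c(1, 1))
  expect_true(all(em$matches$delay >= 0 & em$matches$delay <= 15))

  # partial-overlap interval example: pred [5,15) vs true [0,10) -> 5/15
  pred <- tibble::tibble(label = 1, start = 5, end = 15)
  tru <- tibble::tibble(label = 1, start = 0, end = 10)
  em2 <- event_detection_metrics(pred, tru, 0.5)
  expect_equal(em2$matches$iou, 1 / 3, tolerance = 1e-9)
  expect_false(em2$matches$detected)
  # symmetric in the two spans
  em2b <- event_detection_metrics(tru, pred, 0.5)
  expect_equal(em2b$matches$iou, 1 / 3, tolerance = 1e-9)

  # onset 100 s, first correct window center at 112.3 s -> delay 12.3 s
  tru3 <- tibble::tibble(label = 1, start = 100, end = 160)
  pred3 <- tibble::tibble(label = 1, start = 100, end = 160)
  wt3 <- tibble::tibble(time = c(97.3, 112.3, 127.3), estimate = c(0, 1, 1))
  em3 <- event_detection_metrics(pred3, tru3, 0.5, wt3)
  expect_equal(em3$matches$delay, 12.3)

  # one predicted span never matches two true events
  tru4 <- tibble::tibble(label = c(1, 1), start = c(0, 20), end = c(10, 30))
  pred4 <- tibble::tibble(label = 1, start = 0, end = 30)
  em4 <- event_detection_metrics(pred4, tru4, 0.2)
  expect_equal(sum(em4$matches$iou > 0), 1)

  # overlapping same-label true spans are merged with a warning
  truo <- tibble::tibble(label = c(1, 1), start = c(0, 5), end = c(10, 20))
  expect_warning(em5 <- event_detection_metrics(pred4, truo, 0.5), "merging")
  expect_equal(nrow(em5$matches), 1)
})

test_that("metrics are invariant to a consistent class relabeling", {
  set.seed(65)
  y <- sample(0:2, 40, replace = TRUE)
  yhat <- sample(0:2, 40, replace = TRUE)
  perm <- c(2L, 0L, 1L)
  cm1 <- confusion_metrics(truth = y, estimate = yhat)
  cm2 <- confusion_metrics(truth = perm[y + 1], estimate = perm[yhat + 1])
  expect_equal(cm1$accuracy, cm2$accuracy)
  expect_equal(cm1$macro_f1, cm2$macro_f1, tolerance = 1e-12)
  expect_equal(cohens_kappa(truth = y, estimate = yhat),
               cohens_kappa(truth = perm[y + 1], estimate = perm[yhat + 1]),
               tolerance = 1e-12)
  expect_equal(transition_accuracy(truth = y, estimate = yhat),
               transition_accuracy(truth = perm[y + 1], estimate = perm[yhat + 1]))
})

test_that("evaluate_windows composes the full report and self-evaluates to 1", {
  w <- tibble::tibble(start = seq(0, 135, 15), end = seq(30, 165, 15))
  truth <- c(0, 0, 1, 1, 1, 0, 0, 2, 2, 0)
  d <- tibble::tibble(session = 1, truth = truth, estimate = truth,
                      time = (w$start + w$end) / 2, start = w$start, end = w$end)
  for (k in 0:2) d[[paste0("score_", k)]] <- as.numeric(truth == k)
  ev <- evaluate_windows(d, K = 3)
  expect_s3_class(ev, "sleepgraph_eval")
  expect_equal(ev$classification$accuracy, 1)
  expect_equal(ev$classification$macro_f1, 1)
  expect_equal(ev$classification$kappa, 1)
  expect_equal(ev$temporal$transition_accuracy, 1)
  expect_equal(ev$events$event_f1, 1)
  expect_true(all(ev$matches$iou == 1) || all(ev$events$matches$iou == 1))
  td <- tidy(ev)
  expect_true(all(c("metric", "class", "value") %in% names(td)))
  expect_equal(td$value[td$metric == "accuracy"], 1)
  # report writer round-trips through JSON
  tmp <- tempfile(fileext = ".json")
  write_eval_report(ev, tmp)
  rep <- jsonlite::read_json(tmp)
  expect_equal(rep$classification$accuracy, 1)
})
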