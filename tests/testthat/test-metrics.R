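test_that("confusion counting matches direct tallies", {
  cc <- confusion(c(1, 1, 0), c(1, 0, 0))
  expect_equal(cc$TP, 1)
  expect_equal(cc$FN, 1)
  expect_equal(cc$TN, 1)
  expect_equal(cc$FP, 0)

  perfect <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$FP + perfect$FN, 0)

  set.seed(3)
  y <- sample(0:1, 500, replace = TRUE)
  p <- sample(0:1, 500, replace = TRUE)
  cc <- confusion(y, p)
  expect_equal(cc$TP, sum(y & p))
  expect_equal(cc$TN, sum(!y & !p))
  expect_equal(cc$FP, sum(!y & p))
  expect_equal(cc$FN, sum(y & !p))
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 500)
  expect_error(confusion(0:1, 0), "equal length")
})

test_that("standard metrics evaluate the closed forms", {
  r <- metrics_standard(confusion_counts(TP = 3, TN = 2, FP = 1, FN = 2))
  expect_equal(r$accuracy, 0.625)
  expect_equal(r$sensitivity, 0.6)
  expect_equal(r$specificity, 2 / 3)
  expect_equal(r$f1, 2 / 3)
  expect_equal(r$mcc, 4 / sqrt(240))

  perfect <- metrics_standard(confusion_counts(TP = 7, TN = 5, FP = 0, FN = 0))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "accuracy",
                                "f1", "mcc")]),
               c(sensitivity = 1, specificity = 1, accuracy = 1,
                 f1 = 1, mcc = 1))

  wrong <- metrics_standard(confusion_counts(TP = 0, TN = 0, FP = 6, FN = 6))
  expect_equal(wrong$accuracy, 0)
  expect_equal(wrong$mcc, -1)

  expect_error(metrics_standard(confusion_counts(5, 0, 0, 0)),
               "both classes")
})

test_that("Chou-form metrics reproduce the analytic worked cases", {
  # balanced random classifier
  rand <- metrics_chou(10, 10, N_minus_plus = 5, N_plus_minus = 5)
  expect_equal(rand$accuracy, 0.5)
  expect_equal(rand$mcc, 0)
  # perfect classification
  perf <- metrics_chou(10, 10, 0, 0)
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$mcc, 1)
  # balanced complete misclassification
  worst <- metrics_chou(10, 10, 10, 10)
  expect_equal(worst$sensitivity, 0)
  expect_equal(worst$specificity, 0)
  expect_equal(worst$accuracy, 0)
  expect_equal(worst$mcc, -1)

  expect_error(metrics_chou(0, 10, 0, 0), "positive")
  expect_error(metrics_chou(10, 10, 11, 0), "within")
})

test_that("Chou and standard formulations agree on random valid counts", {
  set.seed(19)
  for (i in 1:1000) {
    np <- sample(1:200, 1)
    nn <- sample(1:200, 1)
    nmp <- sample(0:np, 1)
    npm <- sample(0:nn, 1)
    chou <- metrics_chou(np, nn, nmp, npm)
    std <- metrics_standard(confusion_counts(TP = np - nmp, TN = nn - npm,
                                             FP = npm, FN = nmp))
    expect_equal(unlist(unclass(chou)), unlist(unclass(std)),
                 tolerance = 1e-12)
    expect_gte(chou$mcc, -1)
    expect_lte(chou$mcc, 1)
  }
})

test_that("ROC/AUC equal pair counting, handle ties, and sweep correctly", {
  roc <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(roc$auc, 0.75)
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(roc$points$fpr[nrow(roc$points)], 1)
  expect_equal(roc$points$tpr[nrow(roc$points)], 1)

  expect_equal(roc_curve(c(3, 2, 1, 0), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_curve(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "both classes")

  set.seed(23)
  for (i in 1:10) {
    s <- round(runif(40), 2) # duplicates force tie handling
    y <- sample(0:1, 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    expect_equal(roc_curve(s, y)$auc, oracle_auc(s, y))
    # invariance under strictly monotone transform
    expect_equal(roc_curve(exp(3 * s), y)$auc, roc_curve(s, y)$auc)
  }
})

test_that("AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(29)
  s <- rnorm(100)
  y <- sample(0:1, 100, replace = TRUE)
  want <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                         direction = "<")))
  expect_equal(roc_curve(s, y)$auc, want)
})

test_that("precision-recall sweep matches per-threshold tallies", {
  pr <- precision_recall(c(0.9, 0.1, 0.2, 0.3), c(1, 0, 0, 0))
  expect_true(any(pr$recall == 1 & pr$precision == 1))
  # perfect ranking: precision 1 at every achieved recall
  pr <- precision_recall(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(pr$precision[pr$recall <= 1][1:2], c(1, 1))

  set.seed(31)
  s <- round(runif(50), 2)
  y <- sample(0:1, 50, replace = TRUE)
  pr <- precision_recall(s, y)
  expect_true(all(diff(pr$recall) >= 0))
  for (i in c(1, 10, nrow(pr))) {
    t <- pr$threshold[i]
    pred <- as.integer(s >= t)
    expect_equal(pr$recall[i], sum(y & pred) / sum(y))
    expect_equal(pr$precision[i], sum(y & pred) / sum(pred))
  }
  expect_error(precision_recall(1:3, c(0, 0, 0)), "positive")
})

test_that("stratified folds partition samples with balanced classes", {
  set.seed(37)
  y <- rep(c(1, 0), c(12, 28))
  folds <- acetree:::stratified_folds(y, 4, seed = 5)
  expect_equal(sort(unique(folds)), 1:4)
  expect_equal(as.vector(table(folds)), rep(10L, 4))
  for (f in 1:4) {
    expect_equal(sum(y[folds == f]), 3) # 12 positives dealt over 4 folds
  }
  expect_error(acetree:::stratified_folds(rep(c(1, 0), c(3, 40)), 4, 1),
               "at least k")
})

test_that("k-fold CV tests every sample once and reports per-fold metrics", {
  set.seed(41)
  X <- matrix(rnorm(80 * 2), 80)
  X[1:40, 1] <- X[1:40, 1] + 4
  y <- rep(c(1, 0), each = 40)
  dummy <- function(x_train, y_train, x_test, seed) {
    # monotone score in the informative feature; no training involved
    1 / (1 + exp(-x_test[, 1]))
  }
  cv <- kfold_cv(X, y, 4, dummy, seed = 7)
  expect_length(cv$fold_reports, 4)
  expect_equal(sort(unique(cv$fold_assignments)), 1:4)
  expect_equal(length(cv$scores), 80)
  expect_gte(cv$mean_auc, 0.95)
  expect_equal(cv$pooled_roc$auc, roc_curve(cv$scores, y)$auc)
  # determinism
  cv2 <- kfold_cv(X, y, 4, dummy, seed = 7)
  expect_identical(cv$scores, cv2$scores)
})

test_that("metric reports export to JSON and TSV", {
  r <- metrics_standard(confusion_counts(3, 2, 1, 2), auc = 0.8)
  jp <- tempfile(fileext = ".json")
  tp <- tempfile(fileext = ".tsv")
  write_metrics_report(r, jp, "json")
  write_metrics_report(r, tp, "tsv")
  back <- jsonlite::fromJSON(jp)
  expect_equal(back$accuracy, 0.625)
  tsv <- read.delim(tp)
  expect_equal(tsv$mcc, 4 / sqrt(240))
  roc <- roc_curve(c(0.9, 0.1), c(1, 0))
  rp <- tempfile(fileext = ".tsv")
  write_roc_points(roc, rp)
  expect_equal(nrow(read.delim(rp)), nrow(roc$points))
})
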