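#' Confusion counts for binary classification
#'
#' Counts the four outcomes of a binary prediction. The object also carries
#' the Chou count view: total positives `N+`, total negatives `N-`,
#' misclassified positives `N-+` (= FN) and misclassified negatives `N+-`
#' (= FP), related by `TP = N+ - N-+`, `TN = N- - N+-`.
#'
#' @param labels True labels (0/1, logical, or "positive"/"negative").
#' @param predictions Predicted labels, same encoding and length.
#' @return Object of class `confusion_counts` with elements `TP`, `TN`,
#'   `FP`, `FN`.
#' @examples
#' confusion(c(1, 1, 0), c(1, 0, 0))
#' @export
confusion <- function(labels, predictions) {
  y <- as_binary_labels(labels)
  p <- as_binary_labels(predictions)
  if (length(y) != length(p)) {
    stop("labels and predictions must have equal length")
  }
  # doubles, not integers: metric formulas multiply counts and must not
  # overflow 32-bit integers on large datasets
  structure(list(TP = as.numeric(sum(y == 1 & p == 1)),
                 TN = as.numeric(sum(y == 0 & p == 0)),
                 FP = as.numeric(sum(y == 0 & p == 1)),
                 FN = as.numeric(sum(y == 1 & p == 0))),
            class = "confusion_counts")
}

#' Construct confusion counts directly
#'
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  stopifnot(TP >= 0, TN >= 0, FP >= 0, FN >= 0)
  structure(list(TP = as.numeric(TP), TN = as.numeric(TN),
                 FP = as.numeric(FP), FN = as.numeric(FN)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%g TN=%g FP=%g FN=%g (P=%g, N=%g)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$FN, x$TN + x$FP))
  invisible(x)
}

#' Convert confusion counts to the Chou count view
#'
#' @param c A `confusion_counts` object.
#' @return List with `N_plus`, `N_minus`, `N_minus_plus`, `N_plus_minus`.
#' @export
as_chou_counts <- function(c) {
  list(N_plus = c$TP + c$FN, N_minus = c$TN + c$FP,
       N_minus_plus = c$FN, N_plus_minus = c$FP)
}

new_metrics_report <- function(sensitivity, specificity, accuracy, f1, mcc,
                               auc = NA_real_) {
  structure(list(sensitivity = sensitivity, specificity = specificity,
                 accuracy = accuracy, f1 = f1, mcc = mcc, auc = auc),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> Sn=%.4f Sp=%.4f Acc=%.4f ",
                     "F1=%.4f MCC=%.4f AUC=%s\n"),
              x$sensitivity, x$specificity, x$accuracy, x$f1, x$mcc,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc)))
  invisible(x)
}

#' Standard-form classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/(P+N)`, F1 `2TP/(2TP+FN+FP)`, and Matthews correlation
#' coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention that a zero MCC denominator yields MCC = 0.
#'
#' @param c A `confusion_counts` object; both classes must be represented
#'   (`P > 0` and `N > 0`).
#' @param auc Optional AUC to attach to the report.
#' @return A `metrics_report`.
#' @examples
#' metrics_standard(confusion_counts(TP = 3, TN = 2, FP = 1, FN = 2))
#' @export
metrics_standard <- function(c, auc = NA_real_) {
  P <- c$TP + c$FN
  N <- c$TN + c$FP
  if (P == 0 || N == 0) {
    stop("both classes must be present (P > 0 and N > 0)")
  }
  denom <- sqrt((c$TP + c$FP) * P) * sqrt((c$TN + c$FP) * (c$TN + c$FN))
  mcc <- if (denom == 0) 0 else (c$TP * c$TN - c$FP * c$FN) / denom
  new_metrics_report(
    sensitivity = c$TP / P,
    specificity = c$TN / N,
    accuracy = (c$TP + c$TN) / (P + N),
    f1 = 2 * c$TP / (2 * c$TP + c$FN + c$FP),
    mcc = mcc,
    auc = auc)
}

#' Chou-form classification metrics
#'
#' The same five metrics expressed in per-class total and misclassification
#' counts, which biologists often find more readable: with `N+` positives of
#' which `N-+` are misclassified, and `N-` negatives of which `N+-` are
#' misclassified,
#' \itemize{
#'   \item `Sn = 1 - N-+/N+`
#'   \item `Sp = 1 - N+-/N-`
#'   \item `Acc = 1 - (N-+ + N+-)/(N+ + N-)`
#'   \item `F1 = 2(N+ - N-+) / (2N+ - N-+ + N+-)`
#'   \item `MCC = (1 - (N-+/N+ + N+-/N-)) /
#'     sqrt((1 + (N+- - N-+)/N+)(1 + (N-+ - N+-)/N-))`
#' }
#' This formulation is algebraically identical to [metrics_standard()] under
#' the mapping `TP = N+ - N-+`, `TN = N- - N+-`, `FP = N+-`, `FN = N-+`;
#' the equality is property-tested. A zero MCC denominator yields 0.
#'
#' @param N_plus,N_minus Class totals (positive integers).
#' @param N_minus_plus Misclassified positives, in `[0, N_plus]`.
#' @param N_plus_minus Misclassified negatives, in `[0, N_minus]`.
#' @param auc Optional AUC to attach.
#' @return A `metrics_report`.
#' @examples
#' # balanced random classifier: Acc = 0.5, MCC = 0
#' metrics_chou(10, 10, N_minus_plus = 5, N_plus_minus = 5)
#' @export
metrics_chou <- function(N_plus, N_minus, N_minus_plus, N_plus_minus,
                         auc = NA_real_) {
  if (N_plus <= 0 || N_minus <= 0) {
    stop("class totals must be positive")
  }
  if (N_minus_plus < 0 || N_minus_plus > N_plus ||
      N_plus_minus < 0 || N_plus_minus > N_minus) {
    stop("misclassification counts must lie within their class totals")
  }
  d2 <- (1 + (N_plus_minus - N_minus_plus) / N_plus) *
    (1 + (N_minus_plus - N_plus_minus) / N_minus)
  mcc <- if (d2 <= 0) 0 else {
    (1 - (N_minus_plus / N_plus + N_plus_minus / N_minus)) / sqrt(d2)
  }
  new_metrics_report(
    sensitivity = 1 - N_minus_plus / N_plus,
    specificity = 1 - N_plus_minus / N_minus,
    accuracy = 1 - (N_minus_plus + N_plus_minus) / (N_plus + N_minus),
    f1 = 2 * (N_plus - N_minus_plus) /
      (2 * N_plus - N_minus_plus + N_plus_minus),
    mcc = mcc,
    auc = auc)
}

# Mann-Whitney AUC with 0.5 credit for ties (equals the trapezoidal area
# under the threshold-sweep ROC).
auc_rank <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' Threshold sweep over the unique scores (predict positive when
#' `score >= t`). The reported AUC is the Mann-Whitney pair statistic with
#' 0.5 credit for ties, identical to the trapezoidal area under the swept
#' curve and invariant under strictly monotone score transforms.
#'
#' @param scores Numeric classifier scores (higher = more positive).
#' @param labels Binary labels.
#' @return Object of class `roc_curve`: list with `points` (data.frame
#'   `threshold`, `fpr`, `tpr`, from (0,0) to (1,1)) and `auc`.
#' @examples
#' roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))$auc # 0.75
#' @export
roc_curve <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  last <- !duplicated(ss, fromLast = TRUE) # last index of each unique score
  tpr <- cumsum(ys == 1)[last] / n1
  fpr <- cumsum(ys == 0)[last] / n0
  pts <- data.frame(threshold = c(Inf, ss[last]),
                    fpr = c(0, fpr), tpr = c(0, tpr))
  if (pts$fpr[nrow(pts)] != 1 || pts$tpr[nrow(pts)] != 1) {
    pts <- rbind(pts, data.frame(threshold = -Inf, fpr = 1, tpr = 1))
  }
  structure(list(points = pts, auc = auc_rank(scores, y)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Precision-recall curve
#'
#' Threshold sweep over unique scores (predict positive when `score >= t`).
#' Recall is monotone non-decreasing along the sweep.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels; at least one positive required.
#' @return data.frame with `threshold`, `recall`, `precision`.
#' @export
precision_recall <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1)
  if (n1 == 0) stop("at least one positive sample is required")
  ord <- order(scores, decreasing = TRUE)
  ys <- y[ord]; ss <- scores[ord]
  last <- !duplicated(ss, fromLast = TRUE)
  tp <- cumsum(ys == 1)[last]
  npred <- seq_along(ys)[last]
  data.frame(threshold = ss[last], recall = tp / n1,
             precision = tp / npred)
}

#' Export a metrics report as JSON or TSV
#'
#' @param report A `metrics_report` (or list of them).
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  reports <- if (inherits(report, "metrics_report")) list(report) else report
  df <- do.call(rbind, lapply(reports, function(r)
    as.data.frame(unclass(r))))
  if (format == "json") {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA,
                         pretty = TRUE, na = "null")
  } else {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Export ROC points as TSV
#'
#' @param roc A `roc_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(roc, path) {
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin, so per-fold class counts differ by at most one.
stratified_folds <- function(y, k, seed) {
  y <- as_binary_labels(y)
  if (k < 2L) stop("k must be >= 2")
  if (min(table(y)) < k) stop("each class must have at least k members")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Stratified k-fold cross-validation
#'
#' Splits samples into `k` stratified folds (per-fold class counts within
#' one of each other), trains the supplied pipeline on each training split
#' and scores the held-out fold. Common choices of `k` for this problem are
#' 4, 6, 8 and 10.
#'
#' @param features Feature matrix (samples x features).
#' @param labels Binary labels.
#' @param k Number of folds (>= 2).
#' @param pipeline Function `(x_train, y_train, x_test, seed)` returning
#'   numeric scores for `x_test`; see [fnt_pipeline()].
#' @param seed Master seed: split into one substream for the fold shuffle
#'   and one per fold for the pipeline.
#' @return Object of class `cv_result`: list with `fold_reports` (one
#'   `metrics_report` per fold, at threshold 0.5, each with its fold AUC),
#'   `fold_assignments`, `pooled_roc` (ROC over all held-out scores),
#'   `mean_auc` and `scores` (held-out score per sample).
#' @export
kfold_cv <- function(features, labels, k, pipeline, seed = 1L) {
  y <- as_binary_labels(labels)
  X <- as.matrix(features)
  stopifnot(nrow(X) == length(y))
  seeds <- derive_seeds(seed, k + 1L)
  folds <- stratified_folds(y, k, seeds[1L])
  scores <- numeric(length(y))
  fold_reports <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds == f
    s <- pipeline(X[!te, , drop = FALSE], y[!te], X[te, , drop = FALSE],
                  seed = seeds[f + 1L])
    scores[te] <- s
    cc <- confusion(y[te], as.integer(s >= 0.5))
    fold_reports[[f]] <- metrics_standard(cc, auc = auc_rank(s, y[te]))
  }
  structure(list(fold_reports = fold_reports, fold_assignments = folds,
                 pooled_roc = roc_curve(scores, y),
                 mean_auc = mean(vapply(fold_reports, function(r) r$auc,
                                        numeric(1))),
                 scores = scores),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  k <- length(x$fold_reports)
  cat(sprintf("<cv_result> %d folds: mean AUC = %.4f, pooled AUC = %.4f\n",
              k, x$mean_auc, x$pooled_roc$auc))
  invisible(x)
}
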