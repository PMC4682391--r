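# Kernel models and evaluation protocols: RBF-SVM classification, SVR
# regression, cross-validation, jackknife, and the usual binary metrics.

#' Train a radial-basis SVM affinity classifier
#'
#' A maximum-margin binary classifier with kernel
#' `K(x, x') = exp(-gamma * ||x - x'||^2)` and box constraint `cost`.
#' The positive class is `"high"` binding affinity.
#'
#' @param x scaled feature matrix (rows = complexes).
#' @param labels class labels (`"high"`/`"low"`), both classes present.
#' @param cost SVM penalty parameter C.
#' @param gamma RBF kernel width.
#' @return object of class `affinity_svm` supporting
#'   `predict(object, newdata, type = c("class", "score"))`; scores are
#'   oriented so larger values favour the `"high"` class.
#' @export
train_classifier <- function(x, labels, cost = 1, gamma = 1 / ncol(x)) {
  labels <- as_affinity_factor(labels)
  if (length(unique(labels)) < 2) {
    fail("training labels must contain both classes")
  }
  fit <- e1071::svm(x, labels, type = "C-classification", kernel = "radial",
                    cost = cost, gamma = gamma, scale = FALSE,
                    shrinking = FALSE, fitted = FALSE, cachesize = 4)
  structure(list(fit = fit, cost = cost, gamma = gamma,
                 features = colnames(x)),
            class = "affinity_svm")
}

#' @export
predict.affinity_svm <- function(object, newdata, type = c("class", "score"),
                                 ...) {
  type <- match.arg(type)
  pred <- stats::predict(object$fit, newdata, decision.values = TRUE)
  if (type == "class") return(factor(pred, levels = c("high", "low")))
  dv <- attr(pred, "decision.values")
  score <- dv[, 1]
  # libsvm orients the decision value toward the first named class of the
  # column label; flip if that class is "low" so higher always means "high".
  if (startsWith(colnames(dv)[1], "low")) score <- -score
  unname(score)
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy (as a percentage), sensitivity, specificity and the
#' Matthews correlation coefficient from the four confusion counts, with
#' `"high"` binding affinity as the positive class:
#' accuracy = (TP+TN)/(TP+TN+FP+FN), sensitivity = TP/(TP+FN),
#' specificity = TN/(TN+FP),
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A zero MCC denominator yields MCC = 0; a zero sensitivity or
#' specificity denominator (no positives, or no negatives) is an error.
#'
#' @param tp,tn,fp,fn nonnegative confusion counts.
#' @param auc optional AUC to carry in the report.
#' @return object of class `metrics_report`.
#' @examples
#' compute_metrics(tp = 48, fn = 6, tn = 42, fp = 12)
#' @export
compute_metrics <- function(tp, tn, fp, fn, auc = NA_real_) {
  counts <- c(tp = unname(tp), tn = unname(tn),
              fp = unname(fp), fn = unname(fn))
  tp <- counts[["tp"]]; tn <- counts[["tn"]]
  fp <- counts[["fp"]]; fn <- counts[["fn"]]
  if (any(counts < 0) || any(counts != round(counts))) {
    fail("confusion counts must be nonnegative integers")
  }
  total <- sum(counts)
  if (total == 0) fail("confusion counts sum to zero")
  if (tp + fn == 0) fail("sensitivity undefined: no positive complexes")
  if (tn + fp == 0) fail("specificity undefined: no negative complexes")
  denom <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
  structure(
    list(confusion = as.list(counts),
         accuracy = 100 * (tp + tn) / total,
         sensitivity = tp / (tp + fn),
         specificity = tn / (tn + fp),
         mcc = mcc,
         auc = auc),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  with(x$confusion, cat(sprintf(
    "<metrics_report> TP=%d TN=%d FP=%d FN=%d\n", tp, tn, fp, fn)))
  cat(sprintf("  accuracy   %6.2f%%\n", x$accuracy))
  cat(sprintf("  sensitivity %.3f   specificity %.3f\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  MCC %.3f   AUC %s\n", x$mcc,
              if (is.na(x$auc)) "-" else sprintf("%.3f", x$auc)))
  invisible(x)
}

confusion_from_predictions <- function(pred, truth) {
  pred <- as_affinity_factor(pred)
  truth <- as_affinity_factor(truth)
  c(tp = sum(pred == "high" & truth == "high"),
    tn = sum(pred == "low" & truth == "low"),
    fp = sum(pred == "high" & truth == "low"),
    fn = sum(pred == "low" & truth == "high"))
}

#' Area under the ROC curve
#'
#' The probability that a uniformly drawn positive ("high") complex scores
#' strictly above a uniformly drawn negative one, with ties counted one
#' half (the Mann-Whitney statistic, computed via midranks).
#'
#' @param scores continuous decision scores, larger favouring `"high"`.
#' @param labels class labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as_affinity_factor(labels)
  n_pos <- sum(labels == "high")
  n_neg <- sum(labels == "low")
  if (n_pos == 0 || n_neg == 0) fail("both classes are required for AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "high"]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' @param scores,labels as in [roc_auc()].
#' @return data.frame of `threshold`, `fpr`, `tpr`, sweeping the threshold
#'   through every distinct score (suitable for plotting or TSV export).
#' @export
roc_points <- function(scores, labels) {
  labels <- as_affinity_factor(labels)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  pts <- t(vapply(thr, function(t) {
    pred_pos <- scores >= t
    c(fpr = sum(pred_pos & labels == "low") / sum(labels == "low"),
      tpr = sum(pred_pos & labels == "high") / sum(labels == "high"))
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Stratified k-fold cross-validation of the affinity classifier
#'
#' Folds are stratified by class and fully determined by `(labels, k,
#' seed)`. Within each fold the [-1, 1] feature scaling is re-fit on the
#' training part and applied to the held-out part, so no information leaks
#' from test complexes into the scaling. Confusion counts are pooled over
#' folds and the metrics computed once on the pooled counts; the AUC is
#' computed from the pooled out-of-fold decision scores.
#'
#' @param x unscaled (or consistently scaled) feature matrix.
#' @param labels class labels per row.
#' @param k number of folds; `k = nrow(x)` gives leave-one-out.
#' @param cost,gamma SVM parameters.
#' @param seed fold-assignment seed.
#' @return `metrics_report` with the pooled out-of-fold scores in the
#'   `"scores"` attribute.
#' @export
cross_validate <- function(x, labels, k = 10, cost = 1, gamma = 1 / ncol(x),
                           seed = 1L) {
  labels <- as_affinity_factor(labels)
  folds <- make_folds(labels, k, seed)
  pred <- factor(rep(NA_character_, nrow(x)), levels = c("high", "low"))
  scores <- numeric(nrow(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    xtr <- fit_scaling(x[tr, , drop = FALSE])
    xte <- apply_scaling(x[!tr, , drop = FALSE], xtr)
    model <- train_classifier(xtr, labels[tr], cost = cost, gamma = gamma)
    pred[!tr] <- predict(model, xte, type = "class")
    scores[!tr] <- predict(model, xte, type = "score")
  }
  conf <- confusion_from_predictions(pred, labels)
  rep <- compute_metrics(conf["tp"], conf["tn"], conf["fp"], conf["fn"],
                         auc = roc_auc(scores, labels))
  attr(rep, "scores") <- scores
  attr(rep, "folds") <- folds
  rep
}

#' Stratified holdout evaluation
#'
#' Splits the complexes into training and test sets per class (default
#' 75/25), fits scaling and the classifier on the training part only, and
#' reports test metrics. On a balanced set of 216 complexes the default
#' split gives 162 training and 54 test complexes (81/27 per class).
#'
#' @inheritParams cross_validate
#' @param train_frac training fraction per class.
#' @return list with `train_n`, `test_n`, `train_idx`, and `metrics`
#'   (a `metrics_report` on the test set).
#' @export
holdout_evaluate <- function(x, labels, cost = 1, gamma = 1 / ncol(x),
                             train_frac = 0.75, seed = 1L) {
  labels <- as_affinity_factor(labels)
  if (any(table(labels) < 2)) fail("both classes need at least 2 complexes")
  train_idx <- integer(0)
  with_seed(seed, {
    for (cl in levels(labels)) {
      idx <- which(labels == cl)
      n_tr <- round(length(idx) * train_frac)
      train_idx <- c(train_idx, sample(idx, n_tr))
    }
  })
  train_idx <- sort(train_idx)
  tr <- seq_len(nrow(x)) %in% train_idx
  xtr <- fit_scaling(x[tr, , drop = FALSE])
  xte <- apply_scaling(x[!tr, , drop = FALSE], xtr)
  model <- train_classifier(xtr, labels[tr], cost = cost, gamma = gamma)
  pred <- predict(model, xte, type = "class")
  scores <- predict(model, xte, type = "score")
  conf <- confusion_from_predictions(pred, labels[!tr])
  metrics <- compute_metrics(conf["tp"], conf["tn"], conf["fp"], conf["fn"],
                             auc = roc_auc(scores, labels[!tr]))
  list(train_n = sum(tr), test_n = sum(!tr), train_idx = train_idx,
       metrics = metrics)
}

#' Jackknifed support vector regression of pKd
#'
#' Leave-one-out estimation: each complex's pKd is predicted by an
#' epsilon-insensitive RBF support vector regressor trained on the other
#' n - 1 complexes (scaling re-fit on each training set). Reports the
#' Pearson correlation and mean absolute error of the held-out
#' predictions.
#'
#' @param x feature matrix restricted to the selected properties.
#' @param pkd observed pKd (-log10 Kd) per complex.
#' @param cost,gamma SVR parameters.
#' @param epsilon width of the insensitive tube, in pKd units.
#' @return object of class `regression_report` with `predictions`,
#'   `pearson_r` and `mae`. If the held-out predictions are constant,
#'   `pearson_r` is `NaN` with a warning; `mae` is still reported.
#' @export
jackknife_regress <- function(x, pkd, cost = 1, gamma = 1 / ncol(x),
                              epsilon = 0.1) {
  if (nrow(x) < 3) fail("jackknife needs at least 3 complexes")
  if (length(pkd) != nrow(x) || anyNA(pkd)) {
    fail("pkd must be a complete numeric vector matching the matrix rows")
  }
  preds <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    xtr <- fit_scaling(x[-i, , drop = FALSE])
    xte <- apply_scaling(x[i, , drop = FALSE], xtr)
    fit <- e1071::svm(xtr, pkd[-i], type = "eps-regression",
                      kernel = "radial", cost = cost, gamma = gamma,
                      epsilon = epsilon, scale = FALSE,
                      shrinking = FALSE, fitted = FALSE, cachesize = 4)
    # with no support vectors (targets constant within the tube) the
    # regression function is the bare intercept, which predict() refuses
    preds[i] <- if (fit$tot.nSV == 0) -fit$rho else stats::predict(fit, xte)
  }
  r <- if (stats::sd(preds) == 0) {
    warning("held-out predictions are constant; Pearson r is undefined")
    NaN
  } else {
    stats::cor(preds, pkd)
  }
  structure(list(predictions = preds, pearson_r = r,
                 mae = mean(abs(preds - pkd))),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("<regression_report> n=%d  Pearson r=%.3f  MAE=%.3f pKd\n",
              length(x$predictions), x$pearson_r, x$mae))
  invisible(x)
}

#' Write a metrics report as TSV and/or JSON
#'
#' @param report a `metrics_report` or `regression_report`.
#' @param tsv,json optional output paths (either may be `NULL`).
#' @return invisibly, the flattened report row.
#' @export
write_metrics_report <- function(report, tsv = NULL, json = NULL) {
  if (inherits(report, "metrics_report")) {
    row <- data.frame(tp = report$confusion$tp, tn = report$confusion$tn,
                      fp = report$confusion$fp, fn = report$confusion$fn,
                      accuracy = report$accuracy,
                      sensitivity = report$sensitivity,
                      specificity = report$specificity,
                      mcc = report$mcc, auc = report$auc)
  } else if (inherits(report, "regression_report")) {
    row <- data.frame(n = length(report$predictions),
                      pearson_r = report$pearson_r, mae = report$mae)
  } else {
    fail("unsupported report type")
  }
  if (!is.null(tsv)) {
    utils::write.table(row, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(as.list(row), json, auto_unbox = TRUE, digits = NA)
  }
  invisible(row)
}
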