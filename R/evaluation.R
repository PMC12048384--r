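# Classification metrics: per-class One-vs-Rest confusion counts,
# accuracy / precision / recall / F1, and trapezoidal ROC/AUC.

#' One-vs-Rest confusion matrix
#'
#' Reduces a multiclass prediction to binary counts for one positive
#' class: samples of `positive_class` are positive, all others negative.
#'
#' @param y_true,y_pred Equal-length class vectors.
#' @param positive_class The class treated as positive; must occur in the
#'   class set.
#' @return Object of class `confusion`: list with integer `TP`, `TN`,
#'   `FP`, `FN` and the positive class name.
#' @export
confusion <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal length")
  }
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  if (!positive_class %in% c(y_true, y_pred)) {
    stop("positive_class '", positive_class, "' not present in the class set")
  }
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  structure(list(TP = tp, TN = tn, FP = fp, FN = fn,
                 positive_class = positive_class),
            class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  cat(sprintf("confusion (positive = %s): TP %d, TN %d, FP %d, FN %d\n",
              x$positive_class, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

# metric = 0 with a "zero_denominator" flag when undefined; the flag lets
# callers distinguish a true zero from the degenerate convention.
.safe_ratio <- function(num, den) {
  if (den == 0) structure(0, zero_denominator = TRUE) else num / den
}

#' Classification metrics from a confusion matrix
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`. A zero denominator yields 0 with attribute
#' `zero_denominator = TRUE` (documented convention).
#'
#' @param cm A `confusion` object.
#' @return Scalar metric in `[0, 1]`.
#' @name confusion-metrics
NULL

#' @rdname confusion-metrics
#' @export
accuracy <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  .safe_ratio(cm$TP + cm$TN, cm$TP + cm$TN + cm$FP + cm$FN)
}

#' @rdname confusion-metrics
#' @export
precision <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  .safe_ratio(cm$TP, cm$TP + cm$FP)
}

#' @rdname confusion-metrics
#' @export
recall <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  .safe_ratio(cm$TP, cm$TP + cm$FN)
}

#' @rdname confusion-metrics
#' @export
f1_score <- function(cm) {
  p <- as.numeric(precision(cm))
  r <- as.numeric(recall(cm))
  if (p + r == 0) structure(0, zero_denominator = TRUE)
  else 2 * p * r / (p + r)
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps the decision threshold over the distinct score values (ties
#' grouped into one step), accumulating (FPR, TPR) points from (0, 0) to
#' (1, 1), and integrates by the trapezoidal rule — equivalent to the
#' rank (Mann-Whitney) formulation with tie correction.
#'
#' @param scores Numeric decision scores, higher meaning more positive.
#' @param y_true Binary ground truth: logical, 0/1, or factor whose
#'   second level is positive.
#' @return Object of class `roc_curve`: list with `points` (data frame
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  if (length(scores) != length(y_true)) {
    stop("scores and y_true must have equal length")
  }
  pos <- if (is.factor(y_true)) y_true == levels(y_true)[2] else y_true > 0
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to compute a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  # group tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp_step <- rowsum(as.numeric(p), grp)
  fp_step <- rowsum(as.numeric(!p), grp)
  tpr <- c(0, cumsum(tp_step) / n_pos)
  fpr <- c(0, cumsum(fp_step) / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Evaluate classifiers on a feature subset under One-vs-Rest
#'
#' Fits each requested classifier on the training rows restricted to the
#' selected feature columns, one binary model per class (One-vs-Rest),
#' predicts the held-out rows by the highest per-class score, and reports
#' accuracy, macro (or micro) precision/recall/F1, macro OvR AUC (the
#' unweighted mean of per-class AUCs) and the per-class confusion
#' matrices. Stochastic classifiers are seeded.
#'
#' @param x_train,x_test Numeric matrices restricted to the selected
#'   features.
#' @param y_train,y_test Class labels.
#' @param classifiers Character vector among `"gradient_boosting"`,
#'   `"gaussian_process"`, `"linear_svc"`, `"logistic_regression"`,
#'   `"sgd"` (default: all five).
#' @param average `"macro"` (default) or `"micro"` averaging for
#'   precision/recall/F1.
#' @param seed Integer seed for stochastic classifiers.
#' @return Object of class `evaluation_report`: list with `per_classifier`
#'   (each holding `accuracy`, `precision`, `recall`, `f1`, `auc`,
#'   `per_class` confusion objects, per-class AUCs and scores), `classes`,
#'   `average` and `seed`.
#' @export
evaluate_classifiers <- function(x_train, y_train, x_test, y_test,
                                 classifiers = c("gradient_boosting",
                                                 "gaussian_process",
                                                 "linear_svc",
                                                 "logistic_regression",
                                                 "sgd"),
                                 average = c("macro", "micro"),
                                 seed = 1L) {
  average <- match.arg(average)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  y_train <- as.factor(y_train)
  y_test <- factor(y_test, levels = levels(y_train))
  if (any(table(y_train) == 0)) {
    stop("a class is absent from the training split; use a stratified split")
  }
  if (anyNA(y_test)) stop("test labels outside the training class set")

  report <- list()
  for (clf in classifiers) {
    scores <- ovr_scores(clf, x_train, y_train, x_test, seed = seed)
    pred <- factor(colnames(scores)[max.col(scores, ties.method = "first")],
                   levels = levels(y_train))
    per_class <- lapply(levels(y_train), function(cl) {
      confusion(y_test, pred, cl)
    })
    names(per_class) <- levels(y_train)
    aucs <- vapply(levels(y_train), function(cl) {
      roc_auc(scores[, cl], y_test == cl)$auc
    }, numeric(1))
    if (average == "macro") {
      prec <- mean(vapply(per_class, function(cm) as.numeric(precision(cm)),
                          numeric(1)))
      rec <- mean(vapply(per_class, function(cm) as.numeric(recall(cm)),
                         numeric(1)))
      f1 <- mean(vapply(per_class, function(cm) as.numeric(f1_score(cm)),
                        numeric(1)))
    } else {
      tp <- sum(vapply(per_class, `[[`, numeric(1), "TP"))
      fp <- sum(vapply(per_class, `[[`, numeric(1), "FP"))
      fn <- sum(vapply(per_class, `[[`, numeric(1), "FN"))
      prec <- as.numeric(.safe_ratio(tp, tp + fp))
      rec <- as.numeric(.safe_ratio(tp, tp + fn))
      f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    }
    report[[clf]] <- list(
      accuracy = mean(pred == y_test),
      precision = prec, recall = rec, f1 = f1,
      auc = mean(aucs), per_class_auc = aucs,
      per_class = per_class, scores = scores, predictions = pred
    )
  }
  structure(list(per_classifier = report, classes = levels(y_train),
                 average = average, seed = seed),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("One-vs-Rest evaluation (", x$average, " averages)\n", sep = "")
  for (clf in names(x$per_classifier)) {
    r <- x$per_classifier[[clf]]
    cat(sprintf("  %-20s acc %.3f  prec %.3f  rec %.3f  F1 %.3f  AUC %.3f\n",
                clf, r$accuracy, r$precision, r$recall, r$f1, r$auc))
  }
  invisible(x)
}
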