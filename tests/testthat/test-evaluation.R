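test_that("One-vs-Rest confusion counts match a per-sample tally", {
  y_true <- c("a", "a", "b", "c", "b", "a")
  y_pred <- c("a", "b", "b", "c", "a", "a")
  cm <- confusion(y_true, y_pred, "a")
  expect_equal(cm$TP, 2L)
  expect_equal(cm$FN, 1L)
  expect_equal(cm$FP, 1L)
  expect_equal(cm$TN, 2L)
  expect_equal(cm$TP + cm$TN + cm$FP + cm$FN, 6L)

  # perfect prediction
  cmp <- confusion(y_true, y_true, "b")
  expect_equal(cmp$FP + cmp$FN, 0L)

  # all predicted negative
  cm0 <- confusion(c("a", "a", "a", "b"), rep("b", 4), "a")
  expect_equal(cm0$FN, 3L)
  expect_equal(cm0$TP, 0L)

  set.seed(1)
  for (rep in 1:5) {
    yt <- sample(letters[1:3], 40, replace = TRUE)
    yp <- sample(letters[1:3], 40, replace = TRUE)
    cm <- confusion(yt, yp, "b")
    expect_equal(cm$TP, sum(yt == "b" & yp == "b"))
    expect_equal(cm$FP, sum(yt != "b" & yp == "b"))
    expect_equal(cm$FN, sum(yt == "b" & yp != "b"))
    expect_equal(cm$TN, sum(yt != "b" & yp != "b"))
  }
  expect_error(confusion(c("a", "b"), "a", "a"), "equal length")
  expect_error(confusion(y_true, y_pred, "zzz"), "not present")
})

test_that("metrics reproduce the defining formulas", {
  cm <- structure(list(TP = 50L, TN = 40L, FP = 5L, FN = 5L,
                       positive_class = "x"), class = "confusion")
  expect_equal(accuracy(cm), 0.90)
  expect_equal(precision(cm), 50 / 55)
  expect_equal(recall(cm), 50 / 55)
  expect_equal(f1_score(cm), 50 / 55)  # P = R -> F1 = P

  set.seed(2)
  for (rep in 1:20) {
    k <- as.list(rpois(4, 10))
    names(k) <- c("TP", "TN", "FP", "FN")
    cm <- structure(c(k, positive_class = "x"), class = "confusion")
    p <- if (k$TP + k$FP == 0) 0 else k$TP / (k$TP + k$FP)
    r <- if (k$TP + k$FN == 0) 0 else k$TP / (k$TP + k$FN)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    expect_equal(as.numeric(precision(cm)), p, tolerance = 1e-12)
    expect_equal(as.numeric(recall(cm)), r, tolerance = 1e-12)
    expect_equal(as.numeric(f1_score(cm)), f, tolerance = 1e-12)
    expect_equal(as.numeric(accuracy(cm)),
                 (k$TP + k$TN) / (k$TP + k$TN + k$FP + k$FN),
                 tolerance = 1e-12)
  }
})

test_that("zero denominators yield 0 with a flag", {
  cm <- structure(list(TP = 0L, TN = 10L, FP = 0L, FN = 0L,
                       positive_class = "x"), class = "confusion")
  p <- precision(cm)
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "zero_denominator"))
  r <- recall(cm)
  expect_true(attr(r, "zero_denominator"))
  expect_equal(as.numeric(f1_score(cm)), 0)
})

test_that("ROC endpoints, tie convention and monotonicity hold", {
  y <- c(rep(1, 5), rep(0, 5))
  perfect <- roc_auc(c(5:1 + 10, 5:1), y)
  expect_equal(perfect$auc, 1)

  tied <- roc_auc(rep(0.7, 10), y)
  expect_equal(tied$auc, 0.5)

  set.seed(3)
  r <- roc_auc(rnorm(40), rep(c(0, 1), 20))
  pts <- r$points
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1)
  expect_equal(pts$tpr[nrow(pts)], 1)
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("trapezoidal AUC equals the Mann-Whitney rank statistic", {
  set.seed(4)
  for (rep in 1:10) {
    n <- 200
    y <- runif(n) < 0.4
    scores <- round(rnorm(n), 1)  # rounded to force ties
    auc <- roc_auc(scores, y)$auc
    # tie-corrected U statistic oracle
    r <- rank(scores)
    u <- sum(r[y]) - sum(y) * (sum(y) + 1) / 2
    oracle <- u / (sum(y) * sum(!y))
    expect_equal(auc, oracle, tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(5)
  y <- rep(c(0, 1), 30)
  s <- rnorm(60)
  a1 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a1, tolerance = 1e-12)
  expect_equal(roc_auc(2 * s - 7, y)$auc, a1, tolerance = 1e-12)
})

test_that("all five classifiers separate a linearly separable toy set", {
  toy <- separable_toy()
  ev <- evaluate_classifiers(toy$x, toy$y, toy$x, toy$y, seed = 1)
  for (clf in names(ev$per_classifier)) {
    expect_equal(ev$per_classifier[[clf]]$accuracy, 1.0,
                 info = clf)
  }
})

test_that("report metrics are self-consistent with stored confusions", {
  set.seed(6)
  n <- 60
  x <- matrix(rnorm(n * 5), ncol = 5)
  y <- factor(sample(c("a", "b", "c"), n, replace = TRUE))
  x[y == "a", 1] <- x[y == "a", 1] + 2
  tr <- seq_len(40)
  te <- 41:60
  ev <- evaluate_classifiers(x[tr, ], y[tr], x[te, ], y[te],
                             classifiers = c("linear_svc", "sgd"), seed = 2)
  for (clf in names(ev$per_classifier)) {
    r <- ev$per_classifier[[clf]]
    precs <- vapply(r$per_class, function(cm) as.numeric(precision(cm)),
                    numeric(1))
    recs <- vapply(r$per_class, function(cm) as.numeric(recall(cm)),
                   numeric(1))
    f1s <- vapply(r$per_class, function(cm) as.numeric(f1_score(cm)),
                  numeric(1))
    expect_equal(r$precision, mean(precs), tolerance = 1e-12)
    expect_equal(r$recall, mean(recs), tolerance = 1e-12)
    expect_equal(r$f1, mean(f1s), tolerance = 1e-12)
    expect_equal(r$auc, mean(r$per_class_auc), tolerance = 1e-12)
    # accuracy equals 1 - misclassification rate
    expect_equal(r$accuracy, 1 - mean(r$predictions != y[te]),
                 tolerance = 1e-12)
    expect_true(all(unlist(r[c("accuracy", "precision", "recall", "f1",
                               "auc")]) >= 0))
    expect_true(all(unlist(r[c("accuracy", "precision", "recall", "f1",
                               "auc")]) <= 1))
  }
})

test_that("macro metrics are invariant to class renaming", {
  set.seed(7)
  n <- 50
  x <- matrix(rnorm(n * 4), ncol = 4)
  y <- factor(sample(c("a", "b"), n, replace = TRUE))
  x[y == "b", ] <- x[y == "b", ] + 1.5
  tr <- 1:35; te <- 36:50
  e1 <- evaluate_classifiers(x[tr, ], y[tr], x[te, ], y[te],
                             classifiers = "linear_svc", seed = 3)
  y2 <- factor(ifelse(y == "a", "zz", "aa"))  # reverses level order too
  e2 <- evaluate_classifiers(x[tr, ], y2[tr], x[te, ], y2[te],
                             classifiers = "linear_svc", seed = 3)
  m1 <- e1$per_classifier$linear_svc
  m2 <- e2$per_classifier$linear_svc
  expect_equal(m1$accuracy, m2$accuracy, tolerance = 1e-12)
  expect_equal(m1$precision, m2$precision, tolerance = 1e-12)
  expect_equal(m1$f1, m2$f1, tolerance = 1e-12)
})

test_that("permuted labels give chance-level macro AUC", {
  set.seed(8)
  n <- 200
  x <- matrix(rnorm(n * 6), ncol = 6)
  y <- factor(sample(c("a", "b"), n, replace = TRUE))  # labels independent of x
  tr <- 1:140; te <- 141:200
  ev <- evaluate_classifiers(x[tr, ], y[tr], x[te, ], y[te],
                             classifiers = "logistic_regression", seed = 4)
  expect_lt(abs(ev$per_classifier$logistic_regression$auc - 0.5), 0.15)
})

test_that("a class missing from the training split is an error", {
  x <- matrix(rnorm(20), ncol = 2)
  y <- factor(rep(c("a", "b"), each = 5), levels = c("a", "b", "c"))
  expect_error(
    evaluate_classifiers(x, y, x, y, classifiers = "sgd"),
    "stratified"
  )
})
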