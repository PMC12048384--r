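# One-vs-Rest classifier backends.
#
# Each backend exposes the same contract: given a training matrix, a
# binary 0/1 response and a seed, return a fitted object and a score
# function over new rows (higher score = more positive). The multiclass
# layer in ovr_scores() fits one binary model per class and stacks the
# scores. Classifier internals are delegated to the standard
# implementations (xgboost, kernlab, e1071, glmnet); the SGD linear
# classifier is a small self-contained implementation of the classic
# stochastic-subgradient hinge-loss training loop.

ovr_scores <- function(classifier, x_train, y_train, x_test, seed = 1L) {
  y_train <- as.factor(y_train)
  scores <- matrix(NA_real_, nrow = nrow(x_test), ncol = nlevels(y_train),
                   dimnames = list(NULL, levels(y_train)))
  for (cl in levels(y_train)) {
    y01 <- as.integer(y_train == cl)
    scores[, cl] <- fit_score_binary(classifier, x_train, y01, x_test,
                                     seed = seed)
  }
  scores
}

fit_score_binary <- function(classifier, x, y01, newx, seed = 1L) {
  switch(classifier,
    gradient_boosting = {
      set.seed(seed)
      dtrain <- xgboost::xgb.DMatrix(x, label = y01, nthread = 1L)
      fit <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = 0.1,
                      max_depth = 3L, nthread = 1L),
        data = dtrain, nrounds = 100L, verbose = 0
      )
      predict(fit, xgboost::xgb.DMatrix(newx, nthread = 1L))
    },
    gaussian_process = {
      set.seed(seed)
      yf <- factor(y01, levels = c(0, 1))
      # capture.output: gausspr prints sigma-estimation chatter via cat()
      invisible(utils::capture.output(
        fit <- kernlab::gausspr(x, yf, type = "classification",
                                scaled = FALSE)
      ))
      kernlab::predict(fit, newx, type = "probabilities")[, "1"]
    },
    linear_svc = {
      set.seed(seed)
      yf <- factor(y01, levels = c(0, 1))
      fit <- e1071::svm(x, yf, kernel = "linear", scale = FALSE)
      dv <- attr(predict(fit, newx, decision.values = TRUE),
                 "decision.values")
      # orient decision values so that higher means class "1"
      if (grepl("^1/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
    },
    logistic_regression = {
      # ridge-penalized logistic fit; glmnet needs >= 2 columns
      xp <- if (ncol(x) < 2L) cbind(x, `.pad` = 0) else x
      np <- if (ncol(newx) < 2L) cbind(newx, `.pad` = 0) else newx
      fit <- glmnet::glmnet(xp, y01, family = "binomial", alpha = 0,
                            lambda = 1e-2, standardize = FALSE)
      as.numeric(predict(fit, np, type = "response"))
    },
    sgd = {
      fit <- sgd_linear_fit(x, y01, seed = seed)
      as.numeric(newx %*% fit$w + fit$b)
    },
    stop("unknown classifier '", classifier, "'")
  )
}

#' Linear classifier trained by stochastic gradient descent
#'
#' A linear decision function `w . x + b` trained by the classic
#' stochastic subgradient descent on the L2-regularized hinge loss
#' (`y in {-1, +1}`): per visited sample, `w <- (1 - eta alpha) w` plus
#' `eta y x` when the margin `y (w . x + b)` is below 1. Samples are
#' reshuffled every epoch with a seeded RNG; the learning rate decays as
#' `eta_t = eta0 / (1 + alpha * eta0 * t)`.
#'
#' @param x Numeric training matrix.
#' @param y01 Binary response coded 0/1.
#' @param epochs Passes over the data (default 30).
#' @param alpha L2 regularization strength (default 1e-4).
#' @param eta0 Initial learning rate (default 0.1).
#' @param seed Seed for the epoch shuffles.
#' @return List with weight vector `w` and intercept `b`.
#' @export
sgd_linear_fit <- function(x, y01, epochs = 30L, alpha = 1e-4, eta0 = 0.1,
                           seed = 1L) {
  stopifnot(is.matrix(x), length(y01) == nrow(x))
  set.seed(seed)
  n <- nrow(x)
  y <- ifelse(y01 > 0, 1, -1)
  w <- numeric(ncol(x))
  b <- 0
  t <- 0
  for (ep in seq_len(epochs)) {
    for (i in sample.int(n)) {
      eta <- eta0 / (1 + alpha * eta0 * t)
      margin <- y[i] * (sum(x[i, ] * w) + b)
      w <- (1 - eta * alpha) * w
      if (margin < 1) {
        w <- w + eta * y[i] * x[i, ]
        b <- b + eta * y[i]
      }
      t <- t + 1
    }
  }
  list(w = w, b = b)
}
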