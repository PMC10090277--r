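## Model-quality statistics shared by all modelling stages. The generic
## leave-one-out loop here is deliberately naive (n refits from scratch): it
## is the package's brute-force oracle against which the analytic shortcuts
## (PRESS in fitOLS, the fold loop in plsLooOnc) are checked.

#' Robustness threshold for external validation
#'
#' Models with external-validation R2 strictly above this value are deemed
#' robust.
#' @export
ROBUSTNESS_THRESHOLD <- 0.5

#' External-validation R2
#'
#' `1 - sum((y - yhat)^2) / sum((y - yTrainMean)^2)` over the test set: the
#' squared error of the predictions relative to the naive model that
#' predicts the training-set activity mean for everything. Strictly greater
#' than 0.5 flags a robust model.
#'
#' @param yTest observed test activities.
#' @param yhatTest predicted test activities (same length).
#' @param yTrainMean mean activity of the training set.
#' @return list with `value` and logical `robust`.
#' @export
r2Ext <- function(yTest, yhatTest, yTrainMean) {
  if (length(yTest) != length(yhatTest) || length(yTest) < 1L)
    stop("yTest and yhatTest must have equal positive length")
  denom <- sum((yTest - yTrainMean)^2)
  if (denom == 0)
    stop("all test activities equal the training mean; R2ext undefined")
  val <- 1 - sum((yTest - yhatTest)^2) / denom
  list(value = val, robust = val > ROBUSTNESS_THRESHOLD)
}

#' Brute-force leave-one-out cross-validation
#'
#' Refits the supplied modelling procedure n times, each time holding one
#' row out, and returns `q2 = 1 - PRESS / sum((y - mean(y))^2)`.
#'
#' @param X numeric matrix of predictors.
#' @param y numeric response.
#' @param fit function `(X, y) -> model object`.
#' @param predictFn function `(model, X) -> predictions`; the default
#'   dispatches on the package's model classes.
#' @return the cross-validated R2 (may be negative).
#' @export
looCv <- function(X, y, fit, predictFn = predict) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 rows")
  if (n != length(y)) stop("rows of X must match length of y")
  press <- 0
  for (i in seq_len(n)) {
    model <- tryCatch(fit(X[-i, , drop = FALSE], y[-i]),
                      error = function(e)
                        stop("model fit failed on fold ", i, ": ",
                             conditionMessage(e), call. = FALSE))
    pred <- predictFn(model, X[i, , drop = FALSE])
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}

#' Mean absolute error
#' @param y observed values.
#' @param yhat predicted values (same length).
#' @return mean of |y - yhat|.
#' @export
maeError <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 1L)
    stop("y and yhat must have equal positive length")
  mean(abs(y - yhat))
}

#' Assemble a validation report
#'
#' @param yTrain,yhatTrain observed and fitted training activities.
#' @param yTest,yhatTest observed and predicted test activities (optional).
#' @param q2Loo leave-one-out Q2 if available.
#' @return a [ValidationReport-class].
#' @export
validationReport <- function(yTrain, yhatTrain, yTest = NULL,
                             yhatTest = NULL, q2Loo = NA_real_) {
  r2 <- 1 - sum((yTrain - yhatTrain)^2) / sum((yTrain - mean(yTrain))^2)
  hasTest <- !is.null(yTest) && length(yTest) >= 1L
  ext <- if (hasTest) r2Ext(yTest, yhatTest, mean(yTrain))
         else list(value = NA_real_, robust = NA)
  new("ValidationReport",
      r2 = r2, q2Loo = q2Loo, r2Ext = ext$value,
      maeTrain = maeError(yTrain, yhatTrain),
      maeTest = if (hasTest) maeError(yTest, yhatTest) else NA_real_,
      nTrain = length(yTrain),
      nTest = if (hasTest) length(yTest) else 0L,
      yTrainMean = mean(yTrain), robust = ext$robust)
}

#' Serialize a ValidationReport to a plain list (for JSON reports)
#'
#' The test-set agreement is reported both as the Pearson correlation and as
#' its square, since "correlation coefficient" is used ambiguously for
#' either in the QSAR literature.
#'
#' @param report a [ValidationReport-class].
#' @param yTest,yhatTest optionally re-supply the test vectors so the
#'   correlation-based statistics can be included.
#' @return named list of plain scalars.
#' @export
validationToList <- function(report, yTest = NULL, yhatTest = NULL) {
  out <- list(r2 = report@r2, q2_loo = report@q2Loo, r2_ext = report@r2Ext,
              mae_train = report@maeTrain, mae_test = report@maeTest,
              n_train = report@nTrain, n_test = report@nTest,
              y_train_mean = report@yTrainMean, robust = report@robust)
  if (!is.null(yTest) && length(yTest) > 1L && stats::sd(yTest) > 0 &&
      !is.null(yhatTest) && stats::sd(yhatTest) > 0) {
    r <- stats::cor(yTest, yhatTest)
    out$test_cor <- r
    out$test_cor_squared <- r^2
  }
  out
}

setMethod("show", "ValidationReport", function(object) {
  cat("ValidationReport\n")
  cat(sprintf("  train: n = %d  r2 = %.4f  MAE = %.4f\n",
              object@nTrain, object@r2, object@maeTrain))
  if (!is.na(object@q2Loo))
    cat(sprintf("  LOO:   Q2 = %.4f\n", object@q2Loo))
  if (object@nTest > 0)
    cat(sprintf("  test:  n = %d  R2ext = %.4f (%s)  MAE = %.4f\n",
                object@nTest, object@r2Ext,
                if (isTRUE(object@robust)) "robust" else "not robust",
                object@maeTest))
})
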