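#' Train the elastic-net logistic movement/rest classifier
#'
#' Logistic regression with elastic-net regularization on the best-lag
#' features (one column per channel x feature). The mixing parameter and
#' penalty strength are optimized over a grid by sevenfold
#' cross-validation (folds over whole trials), scoring classification
#' error; the final model is refit on all training frames.
#'
#' @param X n x (channels * 8) matrix of best-lag features.
#' @param labels logical (or 0/1) movement labels per row.
#' @param fold_id integer fold assignment per row.
#' @param alphas elastic-net mixing grid (0 = ridge, 1 = lasso).
#' @param nlambda penalty-strength path length per mixing value.
#' @return object of class `movement_classifier`: list with the fitted
#'   `glmnet` model, `alpha`, `lambda`, and `cv_error`.
#' @export
train_movement_classifier <- function(X, labels, fold_id,
                                      alphas = c(0.1, 0.5, 0.9),
                                      nlambda = 30L) {
  y <- as.integer(labels)
  if (length(unique(y)) < 2) {
    stop("training data contain a single class", call. = FALSE)
  }
  fold_num <- as.integer(factor(fold_id))
  best <- NULL
  for (a in alphas) {
    cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = a,
                            foldid = fold_num, type.measure = "class",
                            nlambda = nlambda)
    err <- min(cv$cvm)
    if (is.null(best) || err < best$err) {
      best <- list(err = err, alpha = a, lambda = cv$lambda.min)
    }
  }
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = best$alpha,
                        lambda = best$lambda)
  structure(list(fit = fit, alpha = best$alpha, lambda = best$lambda,
                 cv_error = best$err), class = "movement_classifier")
}

#' Predict movement probability per frame
#'
#' @param object a `movement_classifier`.
#' @param newdata matrix of best-lag features.
#' @param ... unused.
#' @return numeric vector of movement probabilities.
#' @export
predict.movement_classifier <- function(object, newdata, ...) {
  as.numeric(predict(object$fit, newdata, type = "response"))
}
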