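#' Multivariate partial-least-squares regression (SIMPLS)
#'
#' Fits a PLS regression with a latent space shared across all response
#' columns, using the SIMPLS algorithm (successive rank-one deflation of
#' the cross-product matrix). Components are nested, so coefficient
#' matrices for every component count up to `ncomp` come out of one fit.
#' Column means are folded into an intercept rather than materialized as
#' centered copies of the design, which matters at this problem's design
#' sizes (thousands of lagged columns).
#'
#' @param X n x p predictor matrix.
#' @param Y n x m response matrix.
#' @param ncomp number of latent components.
#' @return object of class `simpls_fit`: list with `x_means`, `y_means`,
#'   `coef` (p x m x ncomp array; slice k is the coefficient matrix using
#'   k components), `intercept` (m x ncomp), and `ncomp`.
#' @export
simpls_fit <- function(X, Y, ncomp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  ncomp <- max(1L, min(ncomp, p, n - 1L))
  xm <- colMeans(X); ym <- colMeans(Y)
  Yc <- Y - rep(ym, each = n)
  # S = Xc' Yc = X' Yc because Yc has zero column sums.
  S <- crossprod(X, Yc)
  R <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp)
  V <- matrix(0, p, ncomp)
  for (a in seq_len(ncomp)) {
    # Dominant right singular vector of S via the m x m eigenproblem.
    q0 <- eigen(crossprod(S), symmetric = TRUE)$vectors[, 1]
    r <- S %*% q0
    t <- X %*% r
    t <- t - mean(t) # equals Xc %*% r
    nt <- sqrt(sum(t^2))
    if (nt < 1e-12) {
      ncomp <- a - 1L
      break
    }
    t <- t / nt
    r <- r / nt
    pv <- crossprod(X, t) # = Xc' t since t sums to zero
    q <- crossprod(Yc, t)
    v <- pv
    if (a > 1) {
      Vp <- V[, seq_len(a - 1), drop = FALSE]
      v <- v - Vp %*% crossprod(Vp, pv)
    }
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; Q[, a] <- q; V[, a] <- v
  }
  if (ncomp < 1) stop("PLS found no usable latent component", call. = FALSE)
  coef <- array(0, c(p, m, ncomp))
  intercept <- matrix(0, m, ncomp)
  B <- matrix(0, p, m)
  for (a in seq_len(ncomp)) {
    B <- B + R[, a] %*% t(Q[, a])
    coef[, , a] <- B
    intercept[, a] <- ym - drop(crossprod(B, xm))
  }
  structure(list(x_means = xm, y_means = ym, coef = coef,
                 intercept = intercept, ncomp = ncomp),
            class = "simpls_fit")
}

#' Predict from a SIMPLS fit
#'
#' @param object a `simpls_fit`.
#' @param newdata matrix of predictors.
#' @param ncomp component count to use (default: the fit's maximum).
#' @param ... unused.
#' @return matrix of predictions (rows match `newdata`).
#' @export
predict.simpls_fit <- function(object, newdata, ncomp = object$ncomp, ...) {
  ncomp <- min(ncomp, object$ncomp)
  B <- object$coef[, , ncomp]
  out <- as.matrix(newdata) %*% B
  out + rep(object$intercept[, ncomp], each = nrow(out))
}

# Predictions for all nested component counts in one GEMM:
# returns an n x m x ncomp array.
simpls_predict_all <- function(fit, newdata) {
  n <- nrow(newdata)
  p <- dim(fit$coef)[1]; m <- dim(fit$coef)[2]; k <- dim(fit$coef)[3]
  flat <- newdata %*% matrix(fit$coef, p, m * k)
  out <- array(flat, c(n, m, k))
  for (a in seq_len(k)) {
    out[, , a] <- out[, , a] + rep(fit$intercept[, a], each = n)
  }
  out
}

#' Train a PLS model with the latent dimension chosen by cross-validation
#'
#' Chooses the component count minimizing the cross-validated mean squared
#' error summed over the response columns (folds formed over whole trials
#' to avoid temporal leakage between adjacent frames), then refits on all
#' rows.
#'
#' @param X n x p predictor matrix (training frames).
#' @param Y n x m response matrix (speed and velocity components).
#' @param fold_id integer fold assignment per row (typically 7 folds by
#'   trial).
#' @param max_comp largest component count examined.
#' @return a `simpls_fit` with extra fields `cv_mse` (per component count)
#'   and `ncomp_selected`.
#' @export
train_pls <- function(X, Y, fold_id, max_comp = 10L) {
  Y <- as.matrix(Y)
  folds <- sort(unique(fold_id))
  if (nrow(X) < length(folds)) {
    stop("fewer training frames than folds", call. = FALSE)
  }
  max_comp <- min(max_comp, ncol(X), nrow(X) - 1L)
  sse <- numeric(max_comp)
  for (f in folds) {
    tr <- fold_id != f
    fit <- simpls_fit(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], max_comp)
    pred <- simpls_predict_all(fit, X[!tr, , drop = FALSE])
    Yte <- Y[!tr, , drop = FALSE]
    for (k in seq_len(max_comp)) {
      kk <- min(k, fit$ncomp)
      sse[k] <- sse[k] + sum((pred[, , kk] - Yte)^2)
    }
  }
  cv_mse <- sse / (nrow(X) * ncol(Y))
  k_best <- which.min(cv_mse)
  fit <- simpls_fit(X, Y, k_best)
  fit$cv_mse <- cv_mse
  fit$ncomp_selected <- fit$ncomp
  fit
}
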