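#' Activation patterns from decoder weights
#'
#' Converts discriminative model weights `W` into forward-model activation
#' patterns `A = Sigma_X W Sigma_S^-1`, where `Sigma_X` is the covariance
#' of the input features and `Sigma_S` the covariance of the model
#' outputs (the kinematics predicted from the training data). Unlike raw
#' decoder weights, activation patterns are interpretable as encoding
#' strength. `Sigma_S` is pseudo-inverted when ill-conditioned.
#'
#' @param W p x m weight matrix (inputs x outputs).
#' @param X n x p training feature matrix.
#' @param S n x m matrix of model outputs on the training data (for a
#'   classifier, the single-column score).
#' @param pinv_tol relative conditioning threshold below which singular
#'   values of `Sigma_S` are treated as zero.
#' @return p x m matrix of activation patterns.
#' @export
compute_activation_patterns <- function(W, X, S, pinv_tol = 1e-10) {
  X <- as.matrix(X); S <- as.matrix(S); W <- as.matrix(W)
  if (nrow(X) < 2) stop("need at least 2 frames to estimate covariances",
                        call. = FALSE)
  sigma_s <- cov(S)
  sv <- svd(sigma_s)
  keep <- sv$d > pinv_tol * max(sv$d)
  if (!any(keep)) stop("output covariance is numerically zero",
                       call. = FALSE)
  sigma_s_inv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  # Sigma_X W Sigma_S^-1 without forming the p x p covariance:
  # cov(X) M = Xc' (Xc M) / (n - 1).
  Xc <- sweep(X, 2, colMeans(X))
  M <- W %*% sigma_s_inv
  crossprod(Xc, Xc %*% M) / (nrow(X) - 1)
}

#' Indices of the top-magnitude fraction of a pattern
#'
#' @param A numeric array/matrix of activation patterns.
#' @param fraction fraction of entries selected by |A| (ties broken by
#'   stable index order).
#' @return integer indices into `A` (column-major for arrays).
#' @export
select_top_fraction <- function(A, fraction = 0.25) {
  a <- abs(as.numeric(A))
  if (length(a) == 0) stop("empty activation pattern", call. = FALSE)
  if (fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]", call. = FALSE)
  }
  k <- ceiling(fraction * length(a))
  order(-a)[seq_len(k)]
}

#' Channel and feature-type importance shares
#'
#' Within the selected top-magnitude entries, the share of the summed
#' absolute activation pattern belonging to each channel and to each
#' feature type, min-max rescaled to `[0, 1]`; plus the peak lag per
#' selected (channel, feature) pair.
#'
#' @param A activation pattern vector for one output, shaped per the
#'   design layout.
#' @param layout design layout data.frame (`channel`, `feature`,
#'   `lag_ms`), as attached to the design matrix.
#' @param selection integer indices from [select_top_fraction()].
#' @param rescale min-max rescale the shares (the raw shares are also
#'   returned).
#' @return list with `channel_share`, `feature_share` (raw, summing to 1
#'   over the selected set), `channel_score`, `feature_score` (0-1
#'   rescaled), and `peak_lags` (data.frame channel/feature/lag_ms).
#' @export
summarize_importance <- function(A, layout, selection, rescale = TRUE) {
  a <- abs(as.numeric(A))
  stopifnot(length(a) == nrow(layout), length(selection) >= 1)
  total <- sum(a[selection])
  sel_layout <- layout[selection, , drop = FALSE]
  ch_share <- tapply(a[selection], factor(sel_layout$channel,
                                          levels = sort(unique(layout$channel))),
                     sum, default = 0) / total
  ft_share <- tapply(a[selection], factor(sel_layout$feature,
                                          levels = sort(unique(layout$feature))),
                     sum, default = 0) / total
  minmax <- function(v) {
    rng <- range(v)
    if (diff(rng) == 0) return(rep(0, length(v)))
    (v - rng[1]) / diff(rng)
  }
  key <- paste(sel_layout$channel, sel_layout$feature)
  peak <- do.call(rbind, lapply(split(seq_along(selection), key), function(i) {
    j <- i[which.max(a[selection][i])]
    data.frame(channel = sel_layout$channel[j],
               feature = sel_layout$feature[j],
               lag_ms = sel_layout$lag_ms[j])
  }))
  list(channel_share = as.numeric(ch_share),
       feature_share = as.numeric(ft_share),
       channel_score = if (rescale) minmax(as.numeric(ch_share)) else
         as.numeric(ch_share),
       feature_score = if (rescale) minmax(as.numeric(ft_share)) else
         as.numeric(ft_share),
       peak_lags = peak)
}

#' Correlate activation patterns across arms
#'
#' Pearson correlation between the absolute values of two activation
#' patterns (e.g. contralateral vs ipsilateral arm models).
#'
#' @param a_contra,a_ipsi activation patterns of identical shape.
#' @return list with `r` and `p`.
#' @export
compare_arm_patterns <- function(a_contra, a_ipsi) {
  if (length(a_contra) != length(a_ipsi)) {
    stop("activation patterns differ in shape", call. = FALSE)
  }
  ct <- cor.test(abs(as.numeric(a_contra)), abs(as.numeric(a_ipsi)))
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Gaussian-kernel topographic projection
#'
#' Projects per-electrode values onto a 2-D grid as a Gaussian-kernel
#' weighted average, normalizing each grid point by the summed kernel
#' contributions of nearby electrodes (so the map is a convex combination
#' of the electrode values).
#'
#' @param coords electrodes x 2 matrix of coordinates.
#' @param values per-electrode values.
#' @param kernel_sd Gaussian kernel standard deviation (coordinate units).
#' @param grid_x,grid_y grid coordinates (defaults span the electrodes).
#' @return list with `x`, `y` and `map` (length(x) x length(y) matrix).
#' @export
project_topography <- function(coords, values, kernel_sd = 1,
                               grid_x = NULL, grid_y = NULL) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 1) stop("need at least one electrode", call. = FALSE)
  if (is.null(grid_x)) {
    grid_x <- seq(min(coords[, 1]) - 2 * kernel_sd,
                  max(coords[, 1]) + 2 * kernel_sd, length.out = 50)
  }
  if (is.null(grid_y)) {
    grid_y <- seq(min(coords[, 2]) - 2 * kernel_sd,
                  max(coords[, 2]) + 2 * kernel_sd, length.out = 50)
  }
  map <- matrix(NA_real_, length(grid_x), length(grid_y))
  for (i in seq_along(grid_x)) {
    for (j in seq_along(grid_y)) {
      d2 <- (coords[, 1] - grid_x[i])^2 + (coords[, 2] - grid_y[j])^2
      w <- exp(-d2 / (2 * kernel_sd^2))
      map[i, j] <- sum(w * values) / sum(w)
    }
  }
  list(x = grid_x, y = grid_y, map = map)
}
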