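#' The analysis lag grid
#'
#' Lags from -1000 to +500 ms in 50 ms steps (31 lags). Negative lags mean
#' the neural activity leads the kinematics.
#'
#' @return numeric vector of lags in milliseconds.
#' @export
lag_grid_ms <- function() seq(-1000, 500, by = 50)

# Lags expressed in frame steps for a given frame step (s).
lags_in_frames <- function(lag_ms = lag_grid_ms(), step_s = 0.05) {
  fr <- lag_ms / 1000 / step_s
  if (any(abs(fr - round(fr)) > 1e-9)) {
    stop("lags must be multiples of the frame step", call. = FALSE)
  }
  as.integer(round(fr))
}

#' Build the lagged design matrix
#'
#' Column (channel c, feature f, lag l) at frame t holds feature (c, f) at
#' window t + l (in frames). Requested frames lacking full lag coverage at
#' the session edges are dropped and reported via the `frames` attribute.
#'
#' Columns are ordered lag-fastest within contiguous (channel, feature)
#' blocks of `length(lag_ms)` columns, which is the block structure the
#' weight-shuffle surrogate permutes.
#'
#' @param features a `feature_tensor` from [extract_features()].
#' @param frame_idx integer indices (into the window grid) of the frames
#'   to predict at.
#' @param lag_ms lag grid in milliseconds.
#' @return numeric matrix `length(frames) x (channels * 8 * n_lags)` with
#'   attributes `frames` (retained frame indices), `layout` (data.frame of
#'   column channel/feature/lag), `n_dropped`.
#' @export
build_lagged_design <- function(features, frame_idx, lag_ms = lag_grid_ms()) {
  stopifnot(inherits(features, "feature_tensor"))
  lf <- lags_in_frames(lag_ms, features$step_s)
  nwin <- dim(features$values)[1]
  nch <- dim(features$values)[2]
  nfeat <- dim(features$values)[3]
  ok <- frame_idx + min(lf) >= 1L & frame_idx + max(lf) <= nwin
  if (!any(ok)) stop("no requested frame has full lag coverage",
                     call. = FALSE)
  frames <- frame_idx[ok]
  nl <- length(lf)
  X <- matrix(NA_real_, length(frames), nch * nfeat * nl)
  layout <- data.frame(
    channel = rep(seq_len(nch), each = nfeat * nl),
    feature = rep(rep(seq_len(nfeat), each = nl), nch),
    lag_ms = rep(lag_ms, nch * nfeat)
  )
  col <- 0L
  for (c in seq_len(nch)) {
    for (f in seq_len(nfeat)) {
      fv <- features$values[, c, f]
      for (l in seq_len(nl)) {
        col <- col + 1L
        X[, col] <- fv[frames + lf[l]]
      }
    }
  }
  colnames(X) <- sprintf("c%d_%s_l%d", layout$channel,
                         features$feature_labels[layout$feature],
                         layout$lag_ms)
  attr(X, "frames") <- frames
  attr(X, "layout") <- layout
  attr(X, "n_dropped") <- sum(!ok)
  X
}

#' Select the best lag per channel and feature
#'
#' For each (channel, feature) pair, picks the lag whose lagged feature
#' series has the maximum absolute Pearson correlation with movement speed
#' over the training frames. Ties are broken toward the smallest absolute
#' lag, then toward the negative (neural-leading) lag. Zero-variance
#' features are assigned lag 0 with a warning.
#'
#' @param design lagged design matrix from [build_lagged_design()]
#'   (training-frame rows).
#' @param speed speed values aligned to the design rows.
#' @param lag_ms lag grid in milliseconds.
#' @return data.frame with `channel`, `feature`, `lag_ms`, `abs_r`, and
#'   `column` (index of the selected design column).
#' @export
select_best_lags <- function(design, speed, lag_ms = lag_grid_ms()) {
  layout <- attr(design, "layout")
  stopifnot(!is.null(layout), length(speed) == nrow(design))
  if (length(unique(speed)) < 2) {
    stop("speed must take at least 2 distinct values", call. = FALSE)
  }
  sds <- col_sds(design)
  r <- rep(0, ncol(design))
  nz <- sds > 0
  if (any(nz)) {
    r[nz] <- drop(cor(design[, nz, drop = FALSE], speed))
  }
  key <- paste(layout$channel, layout$feature, sep = "_")
  groups <- split(seq_len(ncol(design)), key)
  rows <- lapply(groups, function(cols) {
    if (all(sds[cols] == 0)) {
      warning("zero-variance feature; lag set to 0", call. = FALSE)
      pick <- cols[layout$lag_ms[cols] == 0]
    } else {
      ar <- abs(r[cols])
      best <- which(ar == max(ar))
      if (length(best) > 1) {
        lm0 <- layout$lag_ms[cols][best]
        best <- best[order(abs(lm0), lm0)][1]
      }
      pick <- cols[best]
    }
    data.frame(channel = layout$channel[pick], feature = layout$feature[pick],
               lag_ms = layout$lag_ms[pick], abs_r = abs(r[pick]),
               column = pick)
  })
  out <- do.call(rbind, rows)
  out[order(out$channel, out$feature), , drop = FALSE]
}

# Column standard deviations without extra dependencies.
col_sds <- function(x) {
  mu <- colMeans(x)
  sqrt(pmax(colMeans(x^2) - mu^2, 0) * nrow(x) / max(nrow(x) - 1, 1))
}
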