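#' Differentiate a position series into velocity and speed
#'
#' Central differences (one-sided at the ends); speed is the Euclidean
#' norm of the velocity.
#'
#' @param position T x 3 matrix of positions (metres).
#' @param fs sampling rate in Hz.
#' @return list with `velocity` (T x 3, m/s) and `speed` (length T).
#' @export
derive_velocity_speed <- function(position, fs) {
  vel <- central_diff(position, fs)
  list(velocity = vel, speed = sqrt(rowSums(vel^2)))
}

#' Window-average kinematics onto the feature frame grid
#'
#' Averages each kinematic parameter within the same 300 ms / 50 ms
#' sliding windows used for the spectral features, so kinematic frames and
#' feature windows share one time base.
#'
#' @param kin data.frame with column `t` (s) plus numeric kinematic
#'   columns (e.g. `x, y, z, vx, vy, vz, speed`), uniformly sampled.
#' @param fs kinematic sampling rate in Hz.
#' @param win_ms,step_ms window length and shift in milliseconds.
#' @return data.frame of frame-averaged kinematics with `t` set to the
#'   window center times.
#' @export
window_kinematics <- function(kin, fs, win_ms = 300, step_ms = 50) {
  win <- round(win_ms / 1000 * fs)
  step <- round(step_ms / 1000 * fs)
  n <- nrow(kin)
  nw <- n_windows(n, win, step)
  starts <- (seq_len(nw) - 1L) * step
  # Trapezoidal average over win + 1 samples: the mean of a linear signal
  # then equals its value exactly at the window center (start + win/2).
  # The final window reuses the last sample for its (clamped) right edge.
  idx <- pmin(outer(starts, seq_len(win + 1L), "+"), n)
  w <- c(0.5, rep(1, win - 1L), 0.5) / win
  cols <- setdiff(names(kin), "t")
  out <- data.frame(t = kin$t[1] + window_centers(n, fs, win_ms, step_ms))
  for (cl in cols) {
    m <- matrix(kin[[cl]][idx], nw, win + 1L)
    out[[cl]] <- as.numeric(m %*% w)
  }
  out
}

#' Detect movement onset from frame-averaged speed
#'
#' The onset is the first frame whose speed exceeds a fraction (default
#' 10%) of the trial's maximum speed. A manual override hook is provided
#' for visually corrected onsets.
#'
#' @param speed frame-averaged speed values of one trial.
#' @param threshold_frac fraction of the trial maximum used as threshold.
#' @param override optional frame index that bypasses detection.
#' @return list with `onset_frame`, `max_speed`, `threshold`.
#' @export
detect_onset <- function(speed, threshold_frac = 0.1, override = NULL) {
  mx <- max(speed)
  if (!is.finite(mx) || mx <= 0) stop("no movement: all-zero speed",
                                      call. = FALSE)
  thr <- threshold_frac * mx
  if (!is.null(override)) {
    return(list(onset_frame = as.integer(override), max_speed = mx,
                threshold = thr))
  }
  onset <- which(speed > thr)[1]
  if (is.na(onset)) stop("no frame exceeds the onset threshold",
                         call. = FALSE)
  list(onset_frame = onset, max_speed = mx, threshold = thr)
}

#' Movement/rest labels from frame-averaged speed
#'
#' A frame is labeled movement when its speed exceeds `threshold_frac`
#' times the trial-specific maximum speed.
#'
#' @inheritParams detect_onset
#' @return logical vector, `TRUE` for movement frames.
#' @export
label_movement <- function(speed, threshold_frac = 0.1) {
  mx <- max(speed)
  if (!is.finite(mx) || mx <= 0) stop("no movement: all-zero speed",
                                      call. = FALSE)
  speed > threshold_frac * mx
}

#' Frame-level kinematics and labels for a whole session
#'
#' Windows the session kinematics onto the feature grid, then derives
#' per-trial movement onsets and movement/rest labels (thresholding within
#' each trial's frames).
#'
#' @param dataset a `synthetic_dataset` (or any list with `kinematics`,
#'   `kin_fs`, `trial_table`).
#' @param win_ms,step_ms window parameters matching the feature extraction.
#' @param threshold_frac onset/label threshold fraction.
#' @return data.frame of frames: `t`, kinematic columns, `trial_id`
#'   (NA between trials), `movement` (logical), `onset` (logical marker of
#'   each trial's onset frame).
#' @export
frame_kinematics <- function(dataset, win_ms = 300, step_ms = 50,
                             threshold_frac = 0.1) {
  frames <- window_kinematics(dataset$kinematics, dataset$kin_fs,
                              win_ms, step_ms)
  tt <- dataset$trial_table
  frames$trial_id <- NA_integer_
  frames$movement <- FALSE
  frames$onset <- FALSE
  for (i in seq_len(nrow(tt))) {
    in_trial <- frames$t >= tt$t_start[i] & frames$t < tt$t_end[i]
    frames$trial_id[in_trial] <- tt$trial_id[i]
    sp <- frames$speed[in_trial]
    if (max(sp) > 0) {
      frames$movement[in_trial] <- label_movement(sp, threshold_frac)
      on <- detect_onset(sp, threshold_frac)$onset_frame
      frames$onset[which(in_trial)[on]] <- TRUE
    }
  }
  frames
}
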