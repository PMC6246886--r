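#' Minimum-jerk position profile
#'
#' Normalized minimum-jerk (quintic) displacement profile
#' `s(tau) = 10 tau^3 - 15 tau^4 + 6 tau^5` for `tau` in `[0, 1]`. Its peak
#' speed is `15/8 = 1.875` times the average speed `D/T`.
#'
#' @param tau normalized time in `[0, 1]` (values outside are clamped).
#' @return displacement fraction in `[0, 1]`.
#' @export
min_jerk_profile <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Generate center-out reach kinematics for one session
#'
#' Produces one minimum-jerk point-to-point reach per trial from the center
#' target to the trial's assigned cube corner, with static holds before
#' (Hold-A + planning delay) and after (Hold-B) the movement. Target
#' assignment is balanced across the 8 corners and seeded-randomly ordered.
#' Velocity is the central difference of position (one-sided at the trial
#' ends) and speed its Euclidean norm, so stored velocity and
#' differentiated position agree exactly.
#'
#' @param config a [task_config()].
#' @param seed integer seed; defaults to `config$seed`.
#' @return An object of class `reach_trials`: a list with `config`,
#'   `trials` (a list, one element per trial, each with `target_index`
#'   (0-7), `t` (session-time grid, s), `position` / `velocity` (T x 3,
#'   metres and m/s), `speed` (length T), and `epoch_marks` (times of
#'   Hold-A onset, go cue, true movement onset, movement end, trial end)),
#'   and `trial_table` (a data.frame of per-trial epoch times).
#' @export
generate_trials <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "task_config"))
  set.seed(seed)
  n <- config$n_trials
  # Balanced target assignment: counts per corner differ by <= 1.
  base <- rep(0:7, length.out = n)
  targets <- sample(base, n, replace = FALSE)
  corners <- target_positions(config)

  fs <- config$kin_fs
  dur <- trial_duration(config)
  n_samp <- round(dur * fs)
  t_rel <- (seq_len(n_samp) - 1) / fs
  move_on_rel <- config$hold_a_s + config$delay_s
  move_end_rel <- move_on_rel + config$move_s

  trials <- vector("list", n)
  for (i in seq_len(n)) {
    corner <- corners[targets[i] + 1L, ]
    tau <- (t_rel - move_on_rel) / config$move_s
    frac <- min_jerk_profile(tau)
    pos <- outer(frac, corner - config$center) +
      matrix(config$center, n_samp, 3, byrow = TRUE)
    if (config$hold_jitter_sd > 0) {
      pos <- pos + smoothed_jitter(n_samp, 3, fs, config$hold_jitter_sd)
    }
    vel <- central_diff(pos, fs)
    t0 <- (i - 1) * dur
    trials[[i]] <- list(
      target_index = targets[i],
      t = t0 + t_rel,
      position = pos,
      velocity = vel,
      speed = sqrt(rowSums(vel^2)),
      epoch_marks = c(hold_a_on = t0, go_cue = t0 + move_on_rel,
                      move_on = t0 + move_on_rel,
                      move_end = t0 + move_end_rel, t_end = t0 + dur)
    )
  }
  trial_table <- data.frame(
    trial_id = seq_len(n),
    target_index = targets,
    t_start = (seq_len(n) - 1) * dur,
    hold_a_on = (seq_len(n) - 1) * dur,
    delay_on = (seq_len(n) - 1) * dur + config$hold_a_s,
    go_cue = (seq_len(n) - 1) * dur + move_on_rel,
    move_on = (seq_len(n) - 1) * dur + move_on_rel,
    move_end = (seq_len(n) - 1) * dur + move_end_rel,
    t_end = seq_len(n) * dur
  )
  structure(list(config = config, trials = trials, trial_table = trial_table),
            class = "reach_trials")
}

# Slow Gaussian positional jitter (white noise low-passed at ~2 Hz and
# rescaled to the requested SD), emulating hand tremor and motion-capture
# sensor drift. The low cutoff keeps the differentiated jitter speed well
# below the 10%-of-peak movement threshold while still exercising it.
smoothed_jitter <- function(n, ncol, fs, sd_target, cutoff_hz = 2) {
  bf <- signal::butter(2, min(cutoff_hz / (fs / 2), 0.99), type = "low")
  j <- matrix(rnorm(n * ncol), n, ncol)
  j <- apply(j, 2, function(col) signal::filtfilt(bf, col))
  j * sd_target / stats::sd(as.numeric(j))
}

# Central-difference derivative of a T x k matrix sampled at `fs`, with
# one-sided differences at the ends.
central_diff <- function(x, fs) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples to differentiate", call. = FALSE)
  d <- (x[c(2:n, n), , drop = FALSE] - x[c(1, 1:(n - 1)), , drop = FALSE]) *
    fs / 2
  d[1, ] <- (x[2, ] - x[1, ]) * fs
  d[n, ] <- (x[n, ] - x[n - 1, ]) * fs
  d
}

#' Concatenate per-trial kinematics into one session-level series
#'
#' @param trials a `reach_trials` object.
#' @return data.frame with columns `t`, `x`, `y`, `z`, `vx`, `vy`, `vz`,
#'   `speed` on the kinematic sampling grid of the whole session.
#' @export
session_kinematics <- function(trials) {
  stopifnot(inherits(trials, "reach_trials"))
  do.call(rbind, lapply(trials$trials, function(tr) {
    data.frame(t = tr$t, x = tr$position[, 1], y = tr$position[, 2],
               z = tr$position[, 3], vx = tr$velocity[, 1],
               vy = tr$velocity[, 2], vz = tr$velocity[, 3],
               speed = tr$speed)
  }))
}
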