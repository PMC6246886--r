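#' Configuration of the 3D center-out reaching task
#'
#' Describes one recording session of the center-out task: reaches from a
#' central start position to the eight corners of a physical cube, with a
#' center hold (Hold-A), a planning delay, a movement period, and an
#' exterior hold (Hold-B) in every trial.
#'
#' @param n_trials number of trials (at least 8; targets are balanced across
#'   the 8 cube corners, so counts per corner differ by at most one).
#' @param cube_edge edge length of the target cube in metres.
#' @param center 3-vector, workspace position of the central start target
#'   in metres.
#' @param hold_a_s,delay_s,move_s,hold_b_s epoch durations in seconds:
#'   center hold, planning delay, movement period, exterior hold.
#' @param kin_fs sampling rate of the motion-capture (kinematic) stream, Hz.
#' @param hold_jitter_sd standard deviation (metres) of smoothed positional
#'   sensor jitter added to the hand trajectory; 0 disables jitter.
#' @param seed integer seed used by [generate_trials()] when no explicit
#'   seed is passed there.
#'
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_trials = 160L, cube_edge = 0.5,
                        center = c(0, 0, 0),
                        hold_a_s = 1.0, delay_s = 2.0, move_s = 1.0,
                        hold_b_s = 0.5, kin_fs = 120, hold_jitter_sd = 0.002,
                        seed = 1L) {
  durs <- c(hold_a_s = hold_a_s, delay_s = delay_s, move_s = move_s,
            hold_b_s = hold_b_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("all epoch durations must be positive", call. = FALSE)
  }
  if (!is.numeric(n_trials) || n_trials < 8) {
    stop("n_trials must be at least 8 (one per cube corner)", call. = FALSE)
  }
  if (cube_edge <= 0) stop("cube_edge must be positive", call. = FALSE)
  if (length(center) != 3) stop("center must be a 3-vector", call. = FALSE)
  if (kin_fs <= 0) stop("kin_fs must be positive", call. = FALSE)
  structure(list(
    n_trials = as.integer(n_trials), cube_edge = cube_edge,
    center = as.numeric(center), hold_a_s = hold_a_s, delay_s = delay_s,
    move_s = move_s, hold_b_s = hold_b_s, kin_fs = kin_fs,
    hold_jitter_sd = hold_jitter_sd, seed = as.integer(seed)
  ), class = "task_config")
}

#' Cube corner target positions
#'
#' @param config a [task_config()].
#' @return 8 x 3 matrix of target positions (metres); row `i` is target
#'   index `i - 1`. Corners are ordered by the sign pattern of
#'   (x, y, z) offsets, x varying fastest.
#' @export
target_positions <- function(config) {
  signs <- as.matrix(expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)))
  sweep(signs * config$cube_edge / 2, 2, config$center, "+")
}

trial_duration <- function(config) {
  config$hold_a_s + config$delay_s + config$move_s + config$hold_b_s
}
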