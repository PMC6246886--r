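#' Conditioning configuration for raw voltage recordings
#'
#' @param excluded_channels integer indices of channels to drop before
#'   referencing (visual-inspection exclusions; empty by default).
#' @param band two-element band-pass corner frequencies in Hz.
#' @param notch_base mains base frequency in Hz (all harmonics below the
#'   upper band edge are notched).
#' @param notch_bw notch bandwidth in Hz.
#' @return object of class `conditioning_config`.
#' @export
conditioning_config <- function(excluded_channels = integer(0),
                                band = c(0.1, 260), notch_base = 60,
                                notch_bw = 2) {
  stopifnot(length(band) == 2, band[1] > 0, band[1] < band[2])
  structure(list(excluded_channels = as.integer(excluded_channels),
                 band = band, notch_base = notch_base, notch_bw = notch_bw),
            class = "conditioning_config")
}

#' Common-average reference within channel groups
#'
#' Subtracts, samplewise, the mean across each reference group's retained
#' channels (one group per electrode array or amplifier bank).
#'
#' @param volts channels x samples matrix.
#' @param groups list of integer channel-index vectors partitioning the
#'   retained channels; default a single group of all channels.
#' @return matrix of the same shape.
#' @export
common_average_reference <- function(volts, groups = list(seq_len(nrow(volts)))) {
  for (g in groups) {
    if (length(g) < 2) {
      stop("each reference group needs at least 2 retained channels",
           call. = FALSE)
    }
    volts[g, ] <- sweep(volts[g, , drop = FALSE], 2,
                        colMeans(volts[g, , drop = FALSE]))
  }
  volts
}

# Zero-phase band-pass: cascaded 2nd-order Butterworth high-pass and
# 4th-order low-pass, each applied forward-backward. The high-pass is kept
# at low order because sub-hertz corners make higher-order transfer-function
# filters numerically fragile.
bandpass_filter <- function(x, fs, band) {
  nyq <- fs / 2
  if (band[2] >= nyq) stop("band edge at or above Nyquist", call. = FALSE)
  hp <- signal::butter(2, band[1] / nyq, type = "high")
  lp <- signal::butter(4, band[2] / nyq, type = "low")
  x <- signal::filtfilt(hp, x)
  signal::filtfilt(lp, x)
}

# Zero-phase 2nd-order Butterworth band-stop notch at f0 +/- bw/2.
notch_filter <- function(x, fs, f0, bw) {
  nyq <- fs / 2
  ns <- signal::butter(2, c(f0 - bw / 2, f0 + bw / 2) / nyq, type = "stop")
  signal::filtfilt(ns, x)
}

#' Condition a raw multichannel recording
#'
#' Drops excluded channels, applies common-average referencing per group,
#' then a zero-phase Butterworth band-pass and zero-phase notch filters at
#' every harmonic of the mains base frequency below the upper band edge.
#'
#' @param volts channels x samples matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param cfg a [conditioning_config()].
#' @param groups reference groups (see [common_average_reference()]),
#'   defined on the channel indexing of `volts` *after* exclusions.
#' @return list with `voltages` (retained channels x samples), `fs`,
#'   `retained` (original indices of retained channels).
#' @export
condition_recording <- function(volts, fs, cfg = conditioning_config(),
                                groups = NULL) {
  stopifnot(inherits(cfg, "conditioning_config"))
  retained <- setdiff(seq_len(nrow(volts)), cfg$excluded_channels)
  volts <- volts[retained, , drop = FALSE]
  if (is.null(groups)) groups <- list(seq_len(nrow(volts)))
  if (cfg$band[2] >= fs / 2) {
    stop("band-pass edge must lie below Nyquist", call. = FALSE)
  }
  volts <- common_average_reference(volts, groups)
  harmonics <- cfg$notch_base * seq_len(floor((cfg$band[2] - 1e-9) /
                                                cfg$notch_base))
  for (ch in seq_len(nrow(volts))) {
    x <- bandpass_filter(volts[ch, ], fs, cfg$band)
    for (h in harmonics) x <- notch_filter(x, fs, h, cfg$notch_bw)
    volts[ch, ] <- x
  }
  list(voltages = volts, fs = fs, retained = retained)
}

#' Per-trial, per-epoch sample index ranges
#'
#' Converts the trial table's epoch times to 0-based, half-open sample
#' ranges `[start, end)` on the recording grid.
#'
#' @param fs sampling rate in Hz.
#' @param trial_table data.frame with columns `trial_id`, `t_start`,
#'   `hold_a_on`, `go_cue`, `move_on`, `move_end`, `t_end` (seconds).
#' @param n_samples total samples in the recording.
#' @return data.frame with one row per trial x epoch (`hold_a`, `delay`,
#'   `movement`, `hold_b`, `trial`) and columns `start`, `end` (0-based,
#'   half-open).
#' @export
segment_trials <- function(fs, trial_table, n_samples) {
  if (nrow(trial_table) == 0) {
    return(data.frame(trial_id = integer(0), epoch = character(0),
                      start = integer(0), end = integer(0)))
  }
  idx <- function(t) as.integer(round(t * fs))
  rows <- lapply(seq_len(nrow(trial_table)), function(i) {
    tt <- trial_table[i, ]
    data.frame(
      trial_id = tt$trial_id,
      epoch = c("hold_a", "delay", "movement", "hold_b", "trial"),
      start = c(idx(tt$hold_a_on), idx(tt$delay_on), idx(tt$move_on),
                idx(tt$move_end), idx(tt$t_start)),
      end = c(idx(tt$delay_on), idx(tt$go_cue), idx(tt$move_end),
              idx(tt$t_end), idx(tt$t_end))
    )
  })
  out <- do.call(rbind, rows)
  if (any(out$end > n_samples) || any(out$start < 0)) {
    stop("trial epochs extend outside the recording", call. = FALSE)
  }
  out
}
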