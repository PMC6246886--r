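#' The seven canonical spectral bands
#'
#' Band limits chosen to span movement-relevant rhythms while avoiding
#' mains-noise harmonics: theta 4-8, mu 8-12, beta-1 12-24, beta-2 24-34,
#' gamma-1 34-55, gamma-2 65-95, gamma-3 130-175 Hz.
#'
#' @return named list; each element has `range` (Hz) and `label`.
#' @export
band_definitions <- function() {
  list(
    theta  = list(range = c(4, 8),     label = "theta"),
    mu     = list(range = c(8, 12),    label = "mu"),
    beta1  = list(range = c(12, 24),   label = "beta1"),
    beta2  = list(range = c(24, 34),   label = "beta2"),
    gamma1 = list(range = c(34, 55),   label = "gamma1"),
    gamma2 = list(range = c(65, 95),   label = "gamma2"),
    gamma3 = list(range = c(130, 175), label = "gamma3")
  )
}

#' Spectral estimation configuration
#'
#' @param ar_order Burg autoregressive model order.
#' @param win_ms,step_ms sliding-window length and shift in milliseconds.
#' @param bin_centers centers of the 2 Hz estimation bins in Hz.
#' @return object of class `spectral_config`.
#' @export
spectral_config <- function(ar_order = 75L, win_ms = 300, step_ms = 50,
                            bin_centers = seq(3, 253, by = 2)) {
  stopifnot(win_ms > step_ms, ar_order >= 1)
  structure(list(ar_order = as.integer(ar_order), win_ms = win_ms,
                 step_ms = step_ms, bin_centers = bin_centers),
            class = "spectral_config")
}

#' Maximum-entropy (Burg) power spectrum of one window
#'
#' Fits an autoregressive model by Burg recursion and evaluates its power
#' spectral density at the requested bin centers.
#'
#' @param x numeric window of samples.
#' @param fs sampling rate in Hz.
#' @param ar_order AR model order (must be below `length(x)`).
#' @param bin_centers frequencies (Hz) at which to evaluate the density.
#' @return strictly positive power values, one per bin center.
#' @export
mem_spectrum <- function(x, fs, ar_order = 75L,
                         bin_centers = seq(3, 253, by = 2)) {
  if (length(x) <= ar_order) {
    stop("window length must exceed the AR order", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("window contains non-finite samples",
                               call. = FALSE)
  drop(.burg_spectrogram(as.numeric(x), length(x), length(x),
                         as.integer(ar_order), as.numeric(bin_centers), fs))
}

# Number of sliding windows covering a signal of n samples.
n_windows <- function(n, win, step) {
  if (n < win) stop("signal shorter than one window", call. = FALSE)
  (n - win) %/% step + 1L
}

# Window center times (s) for a signal starting at t = 0.
window_centers <- function(n, fs, win_ms, step_ms) {
  win <- round(win_ms / 1000 * fs)
  step <- round(step_ms / 1000 * fs)
  nw <- n_windows(n, win, step)
  ((seq_len(nw) - 1) * step + win / 2) / fs
}

#' Sliding-window maximum-entropy spectrogram of one channel
#'
#' @param x channel signal.
#' @param fs sampling rate in Hz.
#' @param cfg a [spectral_config()].
#' @return matrix windows x bins of AR spectral power; attribute
#'   `centers_s` holds the window center times.
#' @export
sliding_spectrogram <- function(x, fs, cfg = spectral_config()) {
  win <- round(cfg$win_ms / 1000 * fs)
  step <- round(cfg$step_ms / 1000 * fs)
  if (length(x) < win) stop("signal shorter than one window", call. = FALSE)
  out <- .burg_spectrogram(as.numeric(x), as.integer(win), as.integer(step),
                           cfg$ar_order, as.numeric(cfg$bin_centers), fs)
  attr(out, "centers_s") <- window_centers(length(x), fs, cfg$win_ms,
                                           cfg$step_ms)
  out
}

#' Log-transform and z-score a spectrogram against baseline windows
#'
#' @param spect windows x bins power matrix (strictly positive).
#' @param baseline_idx indices of baseline windows (pooled across all
#'   trials of the session).
#' @return windows x bins matrix of z-scores of log power.
#' @export
zscore_bins <- function(spect, baseline_idx) {
  if (length(baseline_idx) < 2) {
    stop("need at least 2 baseline windows", call. = FALSE)
  }
  lg <- log(spect)
  mu <- colMeans(lg[baseline_idx, , drop = FALSE])
  sdv <- apply(lg[baseline_idx, , drop = FALSE], 2, sd)
  if (any(sdv == 0)) stop("zero baseline variance in a frequency bin",
                          call. = FALSE)
  sweep(sweep(lg, 2, mu), 2, sdv, "/")
}

#' Pool z-scored bins into bands and re-z-score
#'
#' Averages member-bin z-values within each canonical band, then z-scores
#' the band series against the pooled baseline windows a second time. The
#' second pass guarantees unit baseline variance per band regardless of how
#' many bins a band contains.
#'
#' @param zbins windows x bins z-score matrix from [zscore_bins()].
#' @param bin_centers bin center frequencies (Hz), one per column.
#' @param baseline_idx baseline window indices.
#' @param bands band definitions as from [band_definitions()].
#' @return windows x 7 matrix of band z-scores (columns named by band).
#' @export
pool_bands_rezscore <- function(zbins, bin_centers, baseline_idx,
                                bands = band_definitions()) {
  out <- matrix(NA_real_, nrow(zbins), length(bands),
                dimnames = list(NULL, names(bands)))
  for (b in seq_along(bands)) {
    members <- which(bin_centers >= bands[[b]]$range[1] &
                       bin_centers <= bands[[b]]$range[2])
    if (length(members) == 0) {
      stop("band ", names(bands)[b], " contains no bins", call. = FALSE)
    }
    avg <- rowMeans(zbins[, members, drop = FALSE])
    mu <- mean(avg[baseline_idx])
    sdv <- sd(avg[baseline_idx])
    if (sdv == 0) stop("zero baseline variance in band ", names(bands)[b],
                       call. = FALSE)
    out[, b] <- (avg - mu) / sdv
  }
  out
}

#' Local motor potential: windowed Savitzky-Golay amplitude, z-scored
#'
#' Fits a second-order polynomial to each 300 ms window by least squares
#' and evaluates it at the window center, then z-scores the resulting
#' series against the pooled baseline windows.
#'
#' @param x channel signal.
#' @param fs sampling rate in Hz.
#' @param baseline_idx baseline window indices; `NULL` skips the z-score
#'   and returns the raw center-evaluated fit.
#' @param win_ms,step_ms window length and shift in milliseconds.
#' @return numeric vector, one value per window.
#' @export
compute_lmp <- function(x, fs, baseline_idx = NULL, win_ms = 300,
                        step_ms = 50) {
  win <- round(win_ms / 1000 * fs)
  step <- round(step_ms / 1000 * fs)
  nw <- n_windows(length(x), win, step)
  # Projection vector: value of the least-squares quadratic fit evaluated
  # at the window center time (offset win/2 from the first sample, i.e.
  # +0.5 on the symmetric sample grid), with closed-form Savitzky-Golay
  # weights from the even/odd moment structure.
  ti <- seq_len(win) - (win + 1) / 2
  tc <- 0.5
  s0 <- win; s2 <- sum(ti^2); s4 <- sum(ti^4)
  d <- s0 * s4 - s2^2
  w0 <- (s4 - s2 * ti^2) / d + tc * ti / s2 +
    tc^2 * (s0 * ti^2 - s2) / d
  starts <- (seq_len(nw) - 1L) * step
  idx <- outer(starts, seq_len(win), "+")
  raw <- as.numeric(matrix(x[idx], nw, win) %*% w0)
  if (is.null(baseline_idx)) return(raw)
  mu <- mean(raw[baseline_idx])
  sdv <- sd(raw[baseline_idx])
  if (sdv == 0) stop("zero baseline variance in the LMP series",
                     call. = FALSE)
  (raw - mu) / sdv
}

#' Baseline window indices for a session
#'
#' A window is a baseline window when its center lies within
#' `[Hold-A onset + 200 ms, Hold-A end]` of some trial.
#'
#' @param centers_s window center times (s).
#' @param trial_table session trial table (needs `hold_a_on`, `delay_on`).
#' @param margin_s offset after Hold-A onset (s).
#' @return integer indices of baseline windows.
#' @export
baseline_windows <- function(centers_s, trial_table, margin_s = 0.2) {
  keep <- rep(FALSE, length(centers_s))
  for (i in seq_len(nrow(trial_table))) {
    keep <- keep | (centers_s >= trial_table$hold_a_on[i] + margin_s &
                      centers_s <= trial_table$delay_on[i])
  }
  which(keep)
}

#' Extract the full feature tensor for a conditioned recording
#'
#' Runs the sliding-window Burg spectrogram per channel, the two-stage
#' (bin-level then band-level) baseline z-scoring, and the z-scored local
#' motor potential, assembling a windows x channels x 8 tensor whose last
#' axis is the 7 canonical bands followed by the LMP.
#'
#' @param volts channels x samples conditioned voltage matrix.
#' @param fs sampling rate in Hz.
#' @param trial_table session trial table.
#' @param cfg a [spectral_config()].
#' @return object of class `feature_tensor`: list with `values`
#'   (windows x channels x 8 array), `centers_s`, `feature_labels`,
#'   `baseline_idx`, `step_s`.
#' @export
extract_features <- function(volts, fs, trial_table,
                             cfg = spectral_config()) {
  nch <- nrow(volts)
  centers <- window_centers(ncol(volts), fs, cfg$win_ms, cfg$step_ms)
  bl <- baseline_windows(centers, trial_table)
  if (length(bl) < 2) stop("no baseline windows found", call. = FALSE)
  labels <- c(names(band_definitions()), "lmp")
  vals <- array(NA_real_, c(length(centers), nch, 8L),
                dimnames = list(NULL, NULL, labels))
  for (ch in seq_len(nch)) {
    spect <- sliding_spectrogram(volts[ch, ], fs, cfg)
    zb <- zscore_bins(spect, bl)
    vals[, ch, 1:7] <- pool_bands_rezscore(zb, cfg$bin_centers, bl)
    vals[, ch, 8] <- compute_lmp(volts[ch, ], fs, bl, cfg$win_ms,
                                 cfg$step_ms)
  }
  structure(list(values = vals, centers_s = centers,
                 feature_labels = labels, baseline_idx = bl,
                 step_s = cfg$step_ms / 1000),
            class = "feature_tensor")
}
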