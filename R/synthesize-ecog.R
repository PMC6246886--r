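# Forward synthesis of multichannel field potentials from kinematics.

# Gaussian band-limited noise via FFT masking with raised-cosine edges,
# normalized to unit standard deviation.
fft_band_noise <- function(n, fs, lo, hi, taper = 1) {
  w <- stats::fft(rnorm(n))
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f) # fold to [0, fs/2]
  m <- numeric(n)
  core <- f >= lo & f <= hi
  m[core] <- 1
  up <- f > lo - taper & f < lo
  m[up] <- 0.5 * (1 + cos(pi * (lo - f[up]) / taper))
  dn <- f > hi & f < hi + taper
  m[dn] <- 0.5 * (1 + cos(pi * (f[dn] - hi) / taper))
  x <- Re(stats::fft(w * m, inverse = TRUE)) / n
  x / sd(x)
}

# 1/f^exponent background noise with unit SD (spectrum flattened below
# 0.5 Hz to keep total power finite).
fft_pink_noise <- function(n, fs, exponent = 1) {
  w <- stats::fft(rnorm(n))
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f <- pmin(f, fs - f)
  m <- pmax(f, 0.5)^(-exponent / 2)
  m[1] <- 0
  x <- Re(stats::fft(w * m, inverse = TRUE)) / n
  x / sd(x)
}

# Shift a series so that out[t] = x[t - lag_s] (lag_ms < 0 pulls future
# values earlier: the output leads the input), padding with edge values.
shift_by_lag <- function(x, lag_ms, fs) {
  k <- round(lag_ms / 1000 * fs)
  n <- length(x)
  idx <- pmin(pmax(seq_len(n) - k, 1L), n)
  x[idx]
}

#' Synthesize a multichannel ECoG recording from reach kinematics
#'
#' Each channel is a sum over the seven canonical bands of a band-limited
#' Gaussian carrier whose instantaneous amplitude is
#' `baseline * exp(w_speed * speed(t - lag) + w_vel . v(t - lag))`, plus a
#' slow DC-coupled component tied to the kinematics (the local motor
#' potential correlate), pink background noise, and optional mains
#' interference. Kinematics are linearly interpolated from the
#' motion-capture rate onto the ECoG sampling grid.
#'
#' @param trials a `reach_trials` object from [generate_trials()].
#' @param encoding a `gt_encoding` from [ground_truth_encoding()] or
#'   [default_encoding()].
#' @param ecog_fs ECoG sampling rate in Hz.
#' @param seed integer seed for carriers and noise.
#' @return An object of class `synthetic_dataset`: list with `voltages`
#'   (channels x samples, microvolts), `fs`, `kin_fs`, `trial_table`,
#'   `kinematics` (session-level data.frame at `kin_fs`), `trials`, and
#'   `encoding`.
#' @export
synthesize_ecog <- function(trials, encoding, ecog_fs = 1200, seed = 1L) {
  stopifnot(inherits(trials, "reach_trials"), inherits(encoding, "gt_encoding"))
  set.seed(seed)
  kin <- session_kinematics(trials)
  kin_fs <- trials$config$kin_fs
  n_samp <- round(nrow(kin) / kin_fs * ecog_fs)
  t_hi <- (seq_len(n_samp) - 1) / ecog_fs
  interp <- function(y) {
    stats::approx(kin$t, y, xout = t_hi, rule = 2)$y
  }
  sp <- interp(kin$speed)
  vel <- cbind(interp(kin$vx), interp(kin$vy), interp(kin$vz))

  bands <- band_definitions()
  nc <- encoding$n_channels
  volts <- matrix(0, nc, n_samp)
  line_phase <- runif(1, 0, 2 * pi)
  for (ch in seq_len(nc)) {
    sig <- numeric(n_samp)
    for (b in seq_along(bands)) {
      carrier <- fft_band_noise(n_samp, ecog_fs, bands[[b]]$range[1],
                                bands[[b]]$range[2])
      lag <- encoding$lag_ms[ch, b]
      expo <- encoding$w_speed[ch, b] * shift_by_lag(sp, lag, ecog_fs)
      for (d in 1:3) {
        if (encoding$w_vel[ch, b, d] != 0) {
          expo <- expo + encoding$w_vel[ch, b, d] *
            shift_by_lag(vel[, d], lag, ecog_fs)
        }
      }
      sig <- sig + encoding$baseline_amp[ch, b] * exp(expo) * carrier
    }
    lmp_lag <- encoding$lmp_lag_ms[ch]
    lmp_dir <- as.numeric(vel %*% encoding$lmp_vel[ch, ])
    sig <- sig + encoding$lmp_speed[ch] * shift_by_lag(sp, lmp_lag, ecog_fs) +
      shift_by_lag(lmp_dir, lmp_lag, ecog_fs)
    if (encoding$pink_amp > 0) {
      sig <- sig + encoding$pink_amp * fft_pink_noise(n_samp, ecog_fs,
                                                      encoding$pink_exponent)
    }
    if (encoding$line_amp > 0) {
      gain <- runif(1, 0.8, 1.2)
      sig <- sig + encoding$line_amp * gain *
        sin(2 * pi * encoding$line_freq * t_hi + line_phase)
    }
    volts[ch, ] <- sig
  }
  structure(list(
    voltages = volts, fs = ecog_fs, kin_fs = kin_fs,
    trial_table = trials$trial_table, kinematics = kin, trials = trials,
    encoding = encoding
  ), class = "synthetic_dataset")
}

#' Generate paired "contralateral"/"ipsilateral" arm datasets
#'
#' Two independent realizations of the same task (fresh trial orders,
#' carriers, and noise) with caller-chosen encodings, emulating separate
#' recording sessions for each arm over one electrode set. Pass identical
#' encodings to simulate a conserved cross-arm representation, or an
#' [orthogonal_encoding()] pair to simulate unrelated representations.
#'
#' @param config a [task_config()].
#' @param encoding_a,encoding_b `gt_encoding` objects of identical shape.
#' @param seed integer seed; the two sessions use distinct derived seeds.
#' @param ecog_fs ECoG sampling rate in Hz.
#' @return list with elements `a` and `b`, each a `synthetic_dataset`.
#' @export
make_paired_arm_datasets <- function(config, encoding_a, encoding_b,
                                     seed = 1L, ecog_fs = 1200) {
  if (encoding_a$n_channels != encoding_b$n_channels) {
    stop("the two encodings must have identical channel counts", call. = FALSE)
  }
  trials_a <- generate_trials(config, seed = seed)
  trials_b <- generate_trials(config, seed = seed + 1L)
  list(
    a = synthesize_ecog(trials_a, encoding_a, ecog_fs, seed = seed + 2L),
    b = synthesize_ecog(trials_b, encoding_b, ecog_fs, seed = seed + 3L)
  )
}
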