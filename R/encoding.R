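#' Ground-truth forward (encoding) model for synthetic ECoG
#'
#' Defines how simulated kinematics drive the simulated field potentials.
#' For every channel and spectral band, the band-limited carrier's
#' instantaneous amplitude is
#' `baseline * exp(w_speed * speed(t - lag) + sum_d w_vel[d] * v_d(t - lag))`,
#' so band log-power is linear in the lagged kinematics. A slow DC-coupled
#' component (`lmp_speed`, `lmp_vel`) tied to the kinematics supports
#' testing of the local motor potential, and pink (1/f) plus optional mains
#' line noise complete the signal.
#'
#' Lag convention: negative lags mean the neural signal leads the
#' kinematics, i.e. the amplitude at time `t` follows the kinematics at
#' `t - lag` (a later time point when `lag < 0`). Lags must sit on the
#' 50 ms analysis grid within [-1000, 500] ms.
#'
#' @param n_channels number of simulated channels.
#' @param w_speed channels x 7 matrix of speed weights (per band).
#' @param w_vel channels x 7 x 3 array of velocity-component weights.
#' @param lag_ms channels x 7 matrix of encoding lags (ms, 50 ms grid).
#' @param baseline_amp channels x 7 matrix of baseline carrier amplitudes
#'   (microvolts).
#' @param lmp_speed,lmp_vel slow-potential couplings: per-channel speed gain
#'   (microvolts per m/s) and channels x 3 velocity gain matrix.
#' @param lmp_lag_ms per-channel lag (ms) of the slow component.
#' @param pink_amp,pink_exponent amplitude (microvolts RMS) and spectral
#'   exponent of the 1/f^exponent background noise.
#' @param line_freq,line_amp mains interference frequency (Hz) and
#'   amplitude (microvolts); `line_amp = 0` disables it.
#'
#' @return An object of class `gt_encoding`.
#' @export
ground_truth_encoding <- function(n_channels, w_speed, w_vel, lag_ms,
                                  baseline_amp, lmp_speed, lmp_vel,
                                  lmp_lag_ms = rep(0, n_channels),
                                  pink_amp = 8, pink_exponent = 1,
                                  line_freq = 60, line_amp = 0) {
  nb <- 7L
  n_channels <- as.integer(n_channels)
  stopifnot(
    all(dim(w_speed) == c(n_channels, nb)),
    all(dim(w_vel) == c(n_channels, nb, 3L)),
    all(dim(lag_ms) == c(n_channels, nb)),
    all(dim(baseline_amp) == c(n_channels, nb)),
    length(lmp_speed) == n_channels,
    all(dim(lmp_vel) == c(n_channels, 3L))
  )
  all_lags <- c(lag_ms, lmp_lag_ms)
  if (any(all_lags %% 50 != 0) || any(all_lags < -1000) || any(all_lags > 500)) {
    stop("encoding lags must lie on the 50 ms grid within [-1000, 500] ms",
         call. = FALSE)
  }
  if (any(!is.finite(c(w_speed, w_vel)))) {
    stop("encoding weights must be finite", call. = FALSE)
  }
  structure(list(
    n_channels = as.integer(n_channels), w_speed = w_speed, w_vel = w_vel,
    lag_ms = lag_ms, baseline_amp = baseline_amp, lmp_speed = lmp_speed,
    lmp_vel = lmp_vel, lmp_lag_ms = lmp_lag_ms, pink_amp = pink_amp,
    pink_exponent = pink_exponent, line_freq = line_freq,
    line_amp = line_amp
  ), class = "gt_encoding")
}

#' Default (strong) encoding used as the study condition
#'
#' Emulates the canonical movement-related spectral picture: event-related
#' desynchronization in mu/beta (negative speed weights), synchronization
#' in the gamma bands (positive weights), a strong slow-potential (LMP)
#' kinematic correlate, and per-channel velocity tuning along random
#' preferred directions so that the channel ensemble spans 3D. Encoding
#' lags are drawn from short neural-leading values on the 50 ms grid.
#'
#' @param n_channels number of channels.
#' @param seed integer seed for the randomized tuning directions and lags.
#' @param strength overall multiplier on all kinematic couplings; 1 is the
#'   default strong-encoding condition, 0 gives a null (no-encoding)
#'   dataset with identical noise statistics.
#' @return A `gt_encoding`.
#' @export
default_encoding <- function(n_channels, seed = 1L, strength = 1) {
  set.seed(seed)
  nb <- 7L
  w_speed <- matrix(0, n_channels, nb)
  w_vel <- array(0, c(n_channels, nb, 3L))
  # ERD in mu (band 2) and beta-1 (band 3); ERS in gamma-2/3 (bands 6, 7).
  w_speed[, 2] <- -0.5
  w_speed[, 3] <- -0.5
  w_speed[, 6] <- 0.9
  w_speed[, 7] <- 0.7
  # Preferred directions: random unit vectors per channel.
  dirs <- matrix(rnorm(n_channels * 3), n_channels, 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  for (b in c(6L, 7L)) w_vel[, b, ] <- 0.6 * dirs
  w_vel[, 3, ] <- -0.3 * dirs
  w_speed <- w_speed * strength
  w_vel <- w_vel * strength
  lag_ms <- matrix(sample(c(-200, -150, -100, -50, 0), n_channels * nb,
                          replace = TRUE), n_channels, nb)
  # Baseline carrier amplitudes fall off with frequency (1/f-like).
  band_centers <- vapply(band_definitions(), function(b) mean(b$range),
                         numeric(1))
  baseline_amp <- matrix(rep(40 / sqrt(band_centers), each = n_channels),
                         n_channels, nb)
  # Sign of the slow-potential speed coupling varies across channels (as it
  # does across cortex), so common-average referencing cannot cancel it.
  lmp_speed <- 10 * strength * sample(c(-1, 1), n_channels, replace = TRUE)
  lmp_vel <- 6 * strength * dirs
  lmp_lag_ms <- sample(c(-100, -50, 0), n_channels, replace = TRUE)
  ground_truth_encoding(n_channels, w_speed, w_vel, lag_ms, baseline_amp,
                        lmp_speed, lmp_vel, lmp_lag_ms)
}

#' Null encoding: no kinematic coupling, identical noise statistics
#'
#' @inheritParams default_encoding
#' @return A `gt_encoding` with all kinematic weights zero.
#' @export
zero_encoding <- function(n_channels, seed = 1L) {
  default_encoding(n_channels, seed = seed, strength = 0)
}

#' Derive an encoding whose weights are uncorrelated with a reference
#'
#' Builds a new encoding with the same shapes, baseline amplitudes, lags
#' and noise statistics as `encoding`, but whose flattened kinematic weight
#' vector (speed, velocity and slow-potential couplings) is exactly
#' Pearson-uncorrelated with the reference's, by projecting random weights
#' against the centered reference vector. Used to simulate a second "arm"
#' whose kinematic encoding shares nothing with the first.
#'
#' @param encoding reference `gt_encoding`.
#' @param seed integer seed.
#' @return A `gt_encoding` with orthogonal kinematic weights.
#' @export
orthogonal_encoding <- function(encoding, seed = 1L) {
  stopifnot(inherits(encoding, "gt_encoding"))
  set.seed(seed)
  ref <- c(encoding$w_speed, encoding$w_vel, encoding$lmp_speed,
           encoding$lmp_vel)
  cand <- rnorm(length(ref), sd = stats::sd(ref))
  refc <- ref - mean(ref)
  if (sum(refc^2) > 0) {
    candc <- cand - mean(cand)
    candc <- candc - sum(candc * refc) / sum(refc^2) * refc
    # Match the reference scale so decoding difficulty is comparable.
    cand <- candc * stats::sd(ref) / stats::sd(candc)
  }
  out <- encoding
  nb <- 7L
  nc <- encoding$n_channels
  i <- 0L
  take <- function(n) {
    v <- cand[(i + 1):(i + n)]
    i <<- i + n
    v
  }
  out$w_speed <- matrix(take(nc * nb), nc, nb)
  out$w_vel <- array(take(nc * nb * 3), c(nc, nb, 3L))
  out$lmp_speed <- take(nc)
  out$lmp_vel <- matrix(take(nc * 3), nc, 3L)
  out
}

#' Flatten an encoding's kinematic weights into one vector
#'
#' @param encoding a `gt_encoding`.
#' @return numeric vector of all kinematic couplings (speed, velocity and
#'   slow-potential weights).
#' @export
encoding_weight_vector <- function(encoding) {
  c(encoding$w_speed, encoding$w_vel, encoding$lmp_speed, encoding$lmp_vel)
}
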