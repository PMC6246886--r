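# Synthetic task generator: kinematics, forward model, paired sessions.

test_that("trial generation balances targets and respects the cube geometry", {
  cfg <- task_config(n_trials = 20, seed = 5, hold_jitter_sd = 0)
  tr <- generate_trials(cfg)
  counts <- table(tr$trial_table$target_index)
  expect_length(counts, 8)
  expect_lte(diff(range(counts)), 1)

  corners <- target_positions(cfg)
  # Adjacent corners differ along one axis by the cube edge.
  expect_equal(sqrt(sum((corners[1, ] - corners[2, ])^2)), 0.5)

  # Every reach ends within 1 cm of its assigned corner.
  for (trial in tr$trials) {
    endpoint <- trial$position[nrow(trial$position), ]
    corner <- corners[trial$target_index + 1, ]
    expect_lt(sqrt(sum((endpoint - corner)^2)), 0.01)
  }
})

test_that("noiseless holds are static and the peak speed matches the quintic profile", {
  cfg <- task_config(n_trials = 8, seed = 2, hold_jitter_sd = 0)
  tr <- generate_trials(cfg)
  trial <- tr$trials[[1]]
  rel_t <- trial$t - trial$t[1]
  hold_a <- rel_t < cfg$hold_a_s
  expect_true(all(trial$speed[hold_a] == 0))

  # Independent oracle: numeric maximization of the quintic speed profile.
  d_reach <- sqrt(3) * cfg$cube_edge / 2 # center to corner
  v_profile <- function(tau) d_reach / cfg$move_s *
    (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
  peak_oracle <- stats::optimize(v_profile, c(0, 1), maximum = TRUE)$objective
  expect_equal(peak_oracle, 1.875 * d_reach / cfg$move_s, tolerance = 1e-9)
  expect_equal(max(trial$speed), peak_oracle, tolerance = 0.01)
})

test_that("stored velocity equals differentiated position", {
  cfg <- task_config(n_trials = 8, seed = 2, hold_jitter_sd = 0)
  tr <- generate_trials(cfg)
  for (trial in tr$trials[1:3]) {
    vel <- reachdecode:::central_diff(trial$position, cfg$kin_fs)
    expect_lt(max(abs(vel - trial$velocity)), 1e-6)
  }
})

test_that("trial generation is bit-reproducible given the seed", {
  cfg <- task_config(n_trials = 12, seed = 9)
  a <- generate_trials(cfg)
  b <- generate_trials(cfg)
  expect_identical(a$trial_table, b$trial_table)
  expect_identical(a$trials[[5]]$position, b$trials[[5]]$position)
})

test_that("band log-power tracks speed when and only when encoded", {
  cfg <- task_config(n_trials = 12, seed = 21)
  tr <- generate_trials(cfg)
  nc <- 4L
  base <- default_encoding(nc, seed = 21, strength = 0)
  # Single coupling: speed on gamma-2 of channel 3 at lag 0.
  enc <- base
  enc$w_speed[3, 6] <- 1.0
  enc$lag_ms[3, 6] <- 0
  ds <- synthesize_ecog(tr, enc, seed = 22)
  ds0 <- synthesize_ecog(tr, base, seed = 22)

  band_logpower <- function(dataset, ch, band) {
    cfg_s <- spectral_config()
    sp <- sliding_spectrogram(dataset$voltages[ch, ], dataset$fs, cfg_s)
    rng <- band_definitions()[[band]]$range
    members <- cfg_s$bin_centers >= rng[1] & cfg_s$bin_centers <= rng[2]
    rowMeans(log(sp[, members, drop = FALSE]))
  }
  frames <- frame_kinematics(ds)
  expect_gte(length(frames$speed), 200)

  # The attainable correlation is bounded by the carrier's intrinsic power
  # fluctuation (a ~30 Hz-wide Gaussian carrier has ~9 spectral degrees of
  # freedom per 300 ms window); measured values sit just around 0.70.
  lp <- band_logpower(ds, 3, "gamma2")
  expect_gt(cor(lp, frames$speed), 0.65)

  # With all weights zero no band of any channel correlates with speed.
  for (ch in 1:2) {
    for (band in c("mu", "gamma2")) {
      expect_lt(abs(cor(band_logpower(ds0, ch, band), frames$speed)), 0.1)
    }
  }
})

test_that("mains interference shows up at the line frequency before notching", {
  cfg <- task_config(n_trials = 8, seed = 31)
  tr <- generate_trials(cfg)
  enc <- default_encoding(2, seed = 31, strength = 0)
  enc$line_amp <- 30
  ds <- synthesize_ecog(tr, enc, seed = 32)
  # FFT periodogram oracle on one channel.
  x <- ds$voltages[1, ]
  n <- length(x)
  pw <- Mod(fft(x - mean(x)))[seq_len(n %/% 2)]^2
  f <- (seq_len(n %/% 2) - 1) * ds$fs / n
  peak_f <- f[which.max(pw)]
  expect_gte(peak_f, 59)
  expect_lte(peak_f, 61)
})

test_that("voltages are finite with bounded energy", {
  ds <- small_dataset()
  expect_false(anyNA(ds$voltages))
  expect_true(all(is.finite(ds$voltages)))
  expect_true(is.finite(var(as.numeric(ds$voltages))))
})

test_that("paired arm datasets honor encoding choices and determinism", {
  cfg <- task_config(n_trials = 8, seed = 41)
  enc <- default_encoding(3, seed = 41)
  same <- make_paired_arm_datasets(cfg, enc, enc, seed = 41)
  expect_identical(encoding_weight_vector(same$a$encoding),
                   encoding_weight_vector(same$b$encoding))

  ortho <- orthogonal_encoding(enc, seed = 42)
  expect_equal(cor(encoding_weight_vector(enc),
                   encoding_weight_vector(ortho)), 0, tolerance = 1e-10)

  again <- make_paired_arm_datasets(cfg, enc, enc, seed = 41)
  expect_identical(same$a$trial_table$target_index,
                   again$a$trial_table$target_index)
  expect_identical(same$a$voltages, again$a$voltages)

  enc_bad <- default_encoding(4, seed = 43)
  expect_error(make_paired_arm_datasets(cfg, enc, enc_bad, seed = 1),
               "channel counts")
})

test_that("invalid task configurations are rejected", {
  expect_error(task_config(n_trials = 4), "at least 8")
  expect_error(task_config(move_s = -1), "positive")
  expect_error(ground_truth_encoding(
    2, w_speed = matrix(0, 2, 7), w_vel = array(0, c(2, 7, 3)),
    lag_ms = matrix(25, 2, 7), baseline_amp = matrix(1, 2, 7),
    lmp_speed = rep(0, 2), lmp_vel = matrix(0, 2, 3)
  ), "50 ms grid")
})
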