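#!/usr/bin/env Rscript

# Stage 1: simulate one recording session of the 3D center-out reaching
# task -- 8 cube-corner targets, Hold-A (1 s) / delay (2 s) / reach /
# Hold-B (0.5 s) epochs -- together with multichannel field potentials
# generated from a known kinematic encoding (ERD in mu/beta, ERS in the
# gamma bands, a slow-potential correlate, pink and mains noise).
#
# Writes: results/demo/kinematics.tsv, trials.tsv, encoding summary.

library(reachdecode)

cfg <- default_run_config("demo", seed = 7)
encoding <- default_encoding(cfg$n_channels, seed = 7)
trials <- generate_trials(cfg$task)
dataset <- synthesize_ecog(trials, encoding, cfg$ecog_fs, seed = 8)

paths <- write_dataset_tsv(dataset, "results/demo")
dir.create("scratch", showWarnings = FALSE)
saveRDS(dataset, "scratch/demo_dataset.rds") # binary cache for later stages

peak <- max(dataset$kinematics$speed)
cat(sprintf("simulated %d trials, %d channels, %.0f s of signal at %d Hz\n",
            cfg$task$n_trials, cfg$n_channels,
            ncol(dataset$voltages) / dataset$fs, dataset$fs))
cat(sprintf("peak hand speed %.2f m/s (minimum-jerk theory: %.2f m/s)\n",
            peak, 1.875 * sqrt(3) * 0.25 / 1))
cat("wrote", paths, "\n")
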