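# Larger shared runs for the acceptance checks (computed once per session).

# Desk-scale run: 16 channels, 160 trials, 20 train/test repeats, 25 weight
# shuffles, generator-default strong encoding.
desk_run <- function(seed = 101) {
  cached(sprintf("desk_run_%d", seed), {
    cfg <- default_run_config("desk", seed = seed)
    enc <- default_encoding(cfg$n_channels, seed = seed, strength = 1)
    trials <- generate_trials(cfg$task, seed = seed)
    ds <- synthesize_ecog(trials, enc, cfg$ecog_fs, seed = seed + 1L)
    prep <- prepare_decoding_data(ds)
    acc <- run_decoding_evaluation(prep, n_repeats = 20, n_shuffles = 25,
                                   seed = seed + 2L)
    list(accuracy = acc)
  })
}

# Null-encoding run: same task and noise statistics, zero kinematic
# coupling.
null_run <- function(seed = 131) {
  cached(sprintf("null_run_%d", seed), {
    cfg <- task_config(n_trials = 64, seed = seed)
    enc <- zero_encoding(8, seed = seed)
    trials <- generate_trials(cfg, seed = seed)
    ds <- synthesize_ecog(trials, enc, seed = seed + 1L)
    prep <- prepare_decoding_data(ds)
    acc <- run_decoding_evaluation(prep, n_repeats = 4, n_shuffles = 0,
                                   seed = seed + 2L)
    list(accuracy = acc, prep = prep)
  })
}

# One paired-arm cross-prediction evaluation: decoders trained on arm A
# folds, tested within-arm and on arm B's matching held-out trials.
cross_pair_eval <- function(enc_a, enc_b, n_trials, n_repeats, seed) {
  cfg <- task_config(n_trials = n_trials, seed = seed)
  pair <- make_paired_arm_datasets(cfg, enc_a, enc_b, seed = seed)
  prep_a <- prepare_decoding_data(pair$a)
  prep_b <- prepare_decoding_data(pair$b)
  splits <- make_splits(prep_a$trial_ids, n_repeats = n_repeats, seed = seed)
  within <- list(); cross <- list()
  for (i in seq_along(splits)) {
    sp <- splits[[i]]
    tr_rows <- prep_a$trial_ids %in% sp$train
    design_tr <- prep_a$design[tr_rows, , drop = FALSE]
    attr(design_tr, "layout") <- attr(prep_a$design, "layout")
    dec <- train_hierarchical_decoder(design_tr,
                                      prep_a$kin[tr_rows, , drop = FALSE])
    te_rows <- prep_a$trial_ids %in% sp$test
    within[[i]] <- cbind(repeat_id = i,
                         evaluate_fold(dec,
                                       prep_a$design[te_rows, , drop = FALSE],
                                       prep_a$kin[te_rows, , drop = FALSE]))
    cross[[i]] <- cbind(repeat_id = i,
                        cross_predict(dec, prep_b, test_trials = sp$test))
  }
  list(within = do.call(rbind, within), cross = do.call(rbind, cross))
}

# Paired-arm runs. The identical-encoding condition uses one pair; the
# orthogonal condition averages over independent orthogonal encoding
# pairs, because any single pair leaves a fixed random kinematic mixing
# in the cross-decoder output whose per-component correlation only
# averages to zero across pairs.
cross_run <- function(mode = c("identical", "orthogonal"), seed = 151) {
  mode <- match.arg(mode)
  cached(sprintf("cross_run_%s_%d", mode, seed), {
    if (mode == "identical") {
      enc <- default_encoding(8, seed = seed, strength = 1)
      cross_pair_eval(enc, enc, n_trials = 96, n_repeats = 8, seed = seed)
    } else {
      runs <- lapply(0:2, function(k) {
        s <- seed + 10L * k
        enc_a <- default_encoding(8, seed = s, strength = 1)
        enc_b <- orthogonal_encoding(enc_a, seed = s + 7L)
        cross_pair_eval(enc_a, enc_b, n_trials = 96, n_repeats = 3,
                        seed = s)
      })
      list(within = do.call(rbind, lapply(runs, `[[`, "within")),
           cross = do.call(rbind, lapply(runs, `[[`, "cross")))
    }
  })
}
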