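# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small synthetic session with strong default encoding.
small_dataset <- function(n_trials = 24, n_channels = 8, seed = 11,
                          strength = 1) {
  key <- sprintf("ds_%d_%d_%d_%s", n_trials, n_channels, seed, strength)
  cached(key, {
    cfg <- task_config(n_trials = n_trials, seed = seed)
    enc <- default_encoding(n_channels, seed = seed, strength = strength)
    tr <- generate_trials(cfg)
    synthesize_ecog(tr, enc, seed = seed + 1L)
  })
}

small_prep <- function(n_trials = 24, n_channels = 8, seed = 11,
                       strength = 1) {
  key <- sprintf("prep_%d_%d_%d_%s", n_trials, n_channels, seed, strength)
  cached(key, prepare_decoding_data(small_dataset(n_trials, n_channels,
                                                  seed, strength)))
}

# Feature tensor assembled directly from given per-(channel, feature)
# window series: windows x channels x 8.
toy_feature_tensor <- function(values, step_s = 0.05) {
  structure(list(
    values = values,
    centers_s = (seq_len(dim(values)[1]) - 1) * step_s + 0.15,
    feature_labels = c(names(band_definitions()), "lmp"),
    baseline_idx = integer(0), step_s = step_s
  ), class = "feature_tensor")
}
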