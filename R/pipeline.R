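#' Default end-to-end run configuration
#'
#' Bundles every stage's parameters with a scale preset: `"desk"` (16
#' channels, 160 trials, 20 train/test repeats, 25 weight shuffles) or
#' `"full"` (100 repeats, 100 shuffles, as in a complete analysis), plus a
#' small `"demo"` preset for quick interactive runs.
#'
#' @param preset scale preset.
#' @param seed global seed; per-stage seeds are derived from it.
#' @return nested configuration list of class `run_config`.
#' @export
default_run_config <- function(preset = c("desk", "demo", "full"),
                               seed = 1L) {
  preset <- match.arg(preset)
  scale <- switch(preset,
    desk = list(n_channels = 16L, n_trials = 160L, n_repeats = 20L,
                n_shuffles = 25L, n_temporal = 0L),
    demo = list(n_channels = 8L, n_trials = 48L, n_repeats = 5L,
                n_shuffles = 10L, n_temporal = 1L),
    full = list(n_channels = 16L, n_trials = 160L, n_repeats = 100L,
                n_shuffles = 100L, n_temporal = 1L)
  )
  structure(list(
    preset = preset, seed = as.integer(seed),
    task = task_config(n_trials = scale$n_trials, seed = seed),
    n_channels = scale$n_channels,
    encoding_strength = 1,
    ecog_fs = 1200,
    conditioning = conditioning_config(),
    spectral = spectral_config(),
    lag_ms = lag_grid_ms(),
    evaluation = list(n_repeats = scale$n_repeats,
                      n_shuffles = scale$n_shuffles,
                      n_temporal = scale$n_temporal,
                      train_frac = 7 / 8, cv_folds = 7L, max_comp = 10L),
    interpretation = list(top_fraction = 0.25)
  ), class = "run_config")
}

#' Validate a run configuration
#'
#' Checks the invariants of every stage's parameters and returns the list
#' of violations (empty when the configuration is runnable).
#'
#' @param config a `run_config`.
#' @return character vector of violations.
#' @export
validate_config <- function(config) {
  v <- character(0)
  say <- function(msg) v <<- c(v, msg)
  tc <- config$task
  if (!inherits(tc, "task_config")) say("task: not a task_config")
  if (config$n_channels < 2) say("n_channels: need at least 2 channels")
  sc <- config$spectral
  nyq <- config$ecog_fs / 2
  if (max(sc$bin_centers) + 1 > nyq) {
    say("SpectralConfig: bin centers reach beyond Nyquist")
  }
  if (any(config$conditioning$band <= 0) ||
      config$conditioning$band[2] >= nyq) {
    say("ConditioningConfig: band outside (0, Nyquist)")
  }
  if (sc$ar_order >= round(sc$win_ms / 1000 * config$ecog_fs)) {
    say("SpectralConfig: AR order not below the window sample count")
  }
  ev <- config$evaluation
  if (ev$train_frac >= 1 || ev$train_frac <= 0) {
    say("evaluation: train fraction must leave a nonempty test set")
  }
  if (ev$cv_folds < 2) say("evaluation: need at least 2 CV folds")
  lg <- config$lag_ms
  if (any(lg %% sc$step_ms != 0)) {
    say("lags must be multiples of the frame step")
  }
  tf <- config$interpretation$top_fraction
  if (tf <= 0 || tf > 1) say("interpretation: top fraction outside (0, 1]")
  v
}

#' Run the end-to-end pipeline on synthetic data
#'
#' Executes simulate, condition, feature-extract, train/evaluate (with
#' weight-shuffle and optional temporal surrogates) and activation-pattern
#' interpretation, returning all stage outputs plus a reproducibility
#' manifest (configuration hash, seeds, stage timings).
#'
#' @param config a `run_config` from [default_run_config()].
#' @return list with `dataset`, `prep`, `accuracy` (accuracy table),
#'   `stats` (actual-vs-surrogate comparisons), `activation` (per-output
#'   activation patterns of a final decoder), `manifest`.
#' @export
run_pipeline <- function(config = default_run_config("demo")) {
  violations <- validate_config(config)
  if (length(violations) > 0) {
    stop("invalid configuration: ", paste(violations, collapse = "; "),
         call. = FALSE)
  }
  t0 <- Sys.time()
  timing <- c()
  tick <- function(stage) {
    timing[stage] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }
  seed <- config$seed
  encoding <- default_encoding(config$n_channels, seed = seed,
                               strength = config$encoding_strength)
  trials <- generate_trials(config$task, seed = seed)
  dataset <- synthesize_ecog(trials, encoding, config$ecog_fs,
                             seed = seed + 1L)
  tick("simulate")
  prep <- prepare_decoding_data(dataset, config$conditioning,
                                config$spectral, config$lag_ms)
  tick("features")
  ev <- config$evaluation
  accuracy <- run_decoding_evaluation(prep, ev$n_repeats, ev$n_shuffles,
                                      ev$n_temporal, seed = seed + 2L,
                                      cv_folds = ev$cv_folds,
                                      max_comp = ev$max_comp,
                                      train_frac = ev$train_frac)
  tick("evaluate")
  stats <- summarize_accuracy_stats(accuracy)
  decoder <- train_hierarchical_decoder(prep$design, prep$kin,
                                        ev$cv_folds, ev$max_comp)
  activation <- decoder_activation_patterns(decoder, prep$design, prep$kin)
  tick("interpret")
  manifest <- list(config_hash = rlang::hash(config), seed = seed,
                   package_version = as.character(utils::packageVersion("reachdecode")),
                   timings_s = as.list(timing))
  list(dataset = dataset, prep = prep, accuracy = accuracy, stats = stats,
       activation = activation, manifest = manifest)
}

#' Rank-sum comparisons of actual vs surrogate accuracies
#'
#' @param accuracy accuracy table from [run_decoding_evaluation()].
#' @param m Bonferroni comparison count.
#' @param alpha family-wise error rate.
#' @return data.frame, one row per metric x surrogate condition.
#' @export
summarize_accuracy_stats <- function(accuracy,
                                     m = bonferroni_comparison_count(),
                                     alpha = 0.05) {
  metrics <- c("speed_r", "vx_r", "vy_r", "vz_r", "targets_hit")
  act <- accuracy[accuracy$condition == "actual", , drop = FALSE]
  out <- list()
  for (cond in setdiff(unique(accuracy$condition), "actual")) {
    sur <- accuracy[accuracy$condition == cond, , drop = FALSE]
    if (nrow(act) < 3 || nrow(sur) < 3) next # too few repeats to compare
    for (met in metrics) {
      row <- compare_distributions(act[[met]], sur[[met]], m, alpha)
      out[[length(out) + 1]] <- cbind(metric = met, condition = cond, row)
    }
  }
  if (length(out) == 0) return(NULL)
  do.call(rbind, out)
}

#' Activation patterns of a trained hierarchical decoder
#'
#' Computes the forward-model activation pattern of the movement-period
#' PLS model (speed and velocity outputs) and of the movement/rest
#' classifier (binary score output).
#'
#' @param decoder a `hierarchical_decoder`.
#' @param design training design matrix.
#' @param kin aligned kinematic frames.
#' @return list with `pls` (p x 4 pattern: speed, vx, vy, vz),
#'   `classifier` (length-p pattern over the best-lag columns expanded to
#'   the design layout), `layout`.
#' @export
decoder_activation_patterns <- function(decoder, design, kin) {
  move <- as.logical(kin$movement)
  Xm <- design[move, , drop = FALSE]
  Y <- as.matrix(kin[move, c("speed", "vx", "vy", "vz")])
  W <- decoder$pls_move$coef[, , decoder$pls_move$ncomp]
  S <- sweep(sweep(Xm, 2, decoder$pls_move$x_means) %*% W, 2,
             decoder$pls_move$y_means, "+")
  a_pls <- compute_activation_patterns(W, Xm, S)

  Xb <- design[, decoder$best_lags$column, drop = FALSE]
  w_cls <- as.numeric(coef(decoder$classifier$fit))[-1]
  score <- Xb %*% w_cls
  a_cls_best <- compute_activation_patterns(matrix(w_cls, ncol = 1), Xb,
                                            score)
  # Expand classifier pattern (one value per channel x feature at its best
  # lag) onto the full design layout for shape-compatible summaries.
  a_cls <- numeric(ncol(design))
  a_cls[decoder$best_lags$column] <- a_cls_best
  list(pls = a_pls, classifier = a_cls, layout = decoder$layout)
}
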