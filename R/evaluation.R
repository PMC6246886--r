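#' Prepare a dataset for decoding
#'
#' Runs conditioning, feature extraction and kinematic framing, selects
#' the decode frames (per trial, from 2 s before the detected movement
#' onset until the trial end), and builds the lagged design matrix over
#' them.
#'
#' @param dataset a `synthetic_dataset` (or equivalent list).
#' @param cond_cfg a [conditioning_config()].
#' @param spec_cfg a [spectral_config()].
#' @param lag_ms lag grid in milliseconds.
#' @param pre_onset_s seconds of pre-onset context retained per trial.
#' @return list with `features`, `frames` (session kinematic frames),
#'   `design` (decode-frame design matrix), `kin` (kinematic frame rows
#'   aligned to the design rows), `trial_ids` (per design row).
#' @export
prepare_decoding_data <- function(dataset,
                                  cond_cfg = conditioning_config(),
                                  spec_cfg = spectral_config(),
                                  lag_ms = lag_grid_ms(),
                                  pre_onset_s = 2) {
  cond <- condition_recording(dataset$voltages, dataset$fs, cond_cfg)
  features <- extract_features(cond$voltages, cond$fs, dataset$trial_table,
                               spec_cfg)
  frames <- frame_kinematics(dataset)
  stopifnot(nrow(frames) == length(features$centers_s))

  tt <- dataset$trial_table
  keep <- rep(FALSE, nrow(frames))
  for (i in seq_len(nrow(tt))) {
    in_trial <- which(frames$trial_id == tt$trial_id[i])
    onset_frame <- in_trial[which(frames$onset[in_trial])[1]]
    if (is.na(onset_frame)) next
    t_on <- frames$t[onset_frame]
    keep <- keep | (frames$t >= t_on - pre_onset_s &
                      frames$t < tt$t_end[i] &
                      !is.na(frames$trial_id) &
                      frames$trial_id == tt$trial_id[i])
  }
  design <- build_lagged_design(features, which(keep), lag_ms)
  rows <- attr(design, "frames")
  kin <- frames[rows, , drop = FALSE]
  list(features = features, frames = frames, design = design, kin = kin,
       trial_ids = kin$trial_id)
}

#' Resampled train/test split plan over whole trials
#'
#' @param trial_ids vector of unique trial ids.
#' @param n_repeats number of independent splits.
#' @param train_frac fraction of trials in the training set.
#' @param seed integer seed.
#' @return list of `n_repeats` lists with elements `train`, `test`.
#' @export
make_splits <- function(trial_ids, n_repeats = 100L, train_frac = 7 / 8,
                        seed = 1L) {
  trial_ids <- unique(trial_ids)
  n <- length(trial_ids)
  if (n < 8) stop("need at least 8 trials to split", call. = FALSE)
  n_train <- round(train_frac * n)
  if (n_train >= n) stop("empty test set: lower train_frac", call. = FALSE)
  set.seed(seed)
  lapply(seq_len(n_repeats), function(i) {
    tr <- sort(sample(trial_ids, n_train))
    list(train = tr, test = setdiff(trial_ids, tr))
  })
}

#' Temporal surrogate kinematics
#'
#' Destroys the neural-kinematic alignment while preserving the kinematic
#' autocorrelation structure: training-trial order is randomly permuted
#' and each trial's kinematic frame series is circularly shifted by a
#' random offset (wrapping from the beginning to the end). Neural features
#' are untouched; per-trial multisets of kinematic frame values are
#' preserved whenever source and slot trials have equal length.
#'
#' @param kin kinematic frame rows of the training set (as from
#'   [prepare_decoding_data()]`$kin`, subset to training trials).
#' @param seed integer seed.
#' @param perm optional explicit trial permutation (trial ids); overrides
#'   the random reordering (the identity permutation with zero shifts
#'   reproduces the original series exactly).
#' @param shifts optional explicit per-trial frame offsets.
#' @return data.frame of the same shape with surrogate `speed`, `vx`,
#'   `vy`, `vz` and `movement` columns (trial ids and times unchanged).
#' @export
temporal_surrogate <- function(kin, seed = 1L, perm = NULL, shifts = NULL) {
  trials <- unique(kin$trial_id)
  if (length(trials) < 2) stop("need at least 2 trials", call. = FALSE)
  set.seed(seed)
  if (is.null(perm)) perm <- sample(trials)
  stopifnot(setequal(perm, trials))
  out <- kin
  cols <- intersect(c("speed", "vx", "vy", "vz", "movement"), names(kin))
  for (i in seq_along(trials)) {
    slot <- which(kin$trial_id == trials[i])
    src <- which(kin$trial_id == perm[i])
    n_src <- length(src)
    shift <- if (is.null(shifts)) sample.int(n_src, 1) - 1L else
      shifts[i] %% n_src
    idx <- src[((seq_len(length(slot)) - 1L + shift) %% n_src) + 1L]
    for (cl in cols) out[[cl]][slot] <- kin[[cl]][idx]
  }
  out
}

#' Weight-shuffle surrogate permutations
#'
#' Random permutations of the (channel, feature) assignment of the decoder
#' weight blocks; the lag structure within each block is kept intact and
#' the movement/rest classifier is untouched.
#'
#' @param decoder a `hierarchical_decoder`.
#' @param n_shuffles number of permutations.
#' @param seed integer seed.
#' @return list of integer permutations of the weight blocks.
#' @export
feature_shuffle_surrogate <- function(decoder, n_shuffles = 100L, seed = 1L) {
  n_blocks <- nrow(decoder$pls_move$coef[, , 1]) / decoder$n_lags
  set.seed(seed)
  lapply(seq_len(n_shuffles), function(i) sample.int(n_blocks))
}

# Pearson r with zero-variance predictions recorded as 0 (flagged via
# attribute).
safe_cor <- function(a, b) {
  if (sd(a) == 0 || sd(b) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  cor(a, b)
}

# Per-trial endpoint displacements by integrating velocity frames.
endpoint_displacements <- function(vel, trial_ids, step_s = 0.05) {
  trials <- unique(trial_ids)
  out <- matrix(NA_real_, length(trials), 3)
  for (i in seq_along(trials)) {
    rows <- trial_ids == trials[i]
    out[i, ] <- colSums(as.matrix(vel)[rows, , drop = FALSE]) * step_s
  }
  rownames(out) <- trials
  out
}

# Accuracy metrics for one prediction against actual kinematics.
prediction_metrics <- function(pred, kin, step_s = 0.05) {
  act_disp <- endpoint_displacements(kin[, c("vx", "vy", "vz")],
                                     kin$trial_id, step_s)
  pred_disp <- endpoint_displacements(pred[, c("vx", "vy", "vz")],
                                      kin$trial_id, step_s)
  data.frame(
    speed_r = as.numeric(safe_cor(pred$speed, kin$speed)),
    vx_r = as.numeric(safe_cor(pred$vx, kin$vx)),
    vy_r = as.numeric(safe_cor(pred$vy, kin$vy)),
    vz_r = as.numeric(safe_cor(pred$vz, kin$vz)),
    targets_hit = score_targets_hit(act_disp, pred_disp)
  )
}

#' Evaluate a trained decoder on held-out frames
#'
#' Computes Pearson correlations between predicted and actual speed and
#' velocity components over the concatenated test frames, plus the
#' percentage of trials whose integrated predicted trajectory ends in the
#' actual endpoint's octant. The same metrics are produced for each
#' weight-shuffle surrogate; per the surrogate design, surrogates retain
#' the actual classifier gating and the actual predicted speed modulates
#' their velocity direction.
#'
#' @param decoder a `hierarchical_decoder`.
#' @param design test-frame design matrix rows.
#' @param kin test kinematic frame rows aligned to `design`.
#' @param shuffles list of weight-block permutations (possibly empty).
#' @param step_s frame step in seconds.
#' @param speed_override optional per-frame speed used to modulate the
#'   main prediction's velocity (used when evaluating temporal-surrogate
#'   PLS models, whose velocity is modulated by the actual model's
#'   predicted speed).
#' @return data.frame with one row per condition: `condition` ("actual" or
#'   "feature-surrogate"), `shuffle` (index or NA), and the five metrics.
#' @export
evaluate_fold <- function(decoder, design, kin, shuffles = list(),
                          step_s = 0.05, speed_override = NULL) {
  pred <- predict_hierarchical(decoder, design,
                               speed_override = speed_override)
  rows <- cbind(condition = "actual", shuffle = NA_integer_,
                prediction_metrics(pred, kin, step_s))
  if (length(shuffles) > 0) {
    sur_rows <- lapply(seq_along(shuffles), function(s) {
      sur <- predict_hierarchical(decoder, design,
                                  block_perm = shuffles[[s]],
                                  speed_override = pred$speed)
      cbind(condition = "feature-surrogate", shuffle = s,
            prediction_metrics(sur, kin, step_s))
    })
    rows <- rbind(rows, do.call(rbind, sur_rows))
  }
  rows
}

#' Resampled evaluation of the hierarchical decoder
#'
#' The top-level evaluation driver: repeatedly samples 7/8 of the trials
#' for training, trains the hierarchical decoder, and evaluates it on the
#' held-out trials together with weight-shuffle surrogates and (optional)
#' temporal-surrogate models trained on circularly shifted kinematics.
#'
#' @param prep output of [prepare_decoding_data()].
#' @param n_repeats number of resampled train/test splits.
#' @param n_shuffles weight-shuffle surrogates per repeat.
#' @param n_temporal temporal-surrogate models per repeat (0 disables).
#' @param seed integer seed governing splits, shuffles and surrogates.
#' @param cv_folds fold count for internal cross-validation.
#' @param max_comp largest PLS component count examined.
#' @param train_frac fraction of trials used for training.
#' @return data.frame accuracy table: `repeat_id`, `condition`, `shuffle`,
#'   `speed_r`, `vx_r`, `vy_r`, `vz_r`, `targets_hit`.
#' @export
run_decoding_evaluation <- function(prep, n_repeats = 20L, n_shuffles = 25L,
                                    n_temporal = 0L, seed = 1L,
                                    cv_folds = 7L, max_comp = 10L,
                                    train_frac = 7 / 8) {
  splits <- make_splits(prep$trial_ids, n_repeats, train_frac, seed)
  out <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    sp <- splits[[rep_i]]
    tr_rows <- prep$trial_ids %in% sp$train
    te_rows <- prep$trial_ids %in% sp$test
    design_tr <- prep$design[tr_rows, , drop = FALSE]
    attr(design_tr, "layout") <- attr(prep$design, "layout")
    design_te <- prep$design[te_rows, , drop = FALSE]
    kin_tr <- prep$kin[tr_rows, , drop = FALSE]
    kin_te <- prep$kin[te_rows, , drop = FALSE]

    decoder <- train_hierarchical_decoder(design_tr, kin_tr, cv_folds,
                                          max_comp)
    shuffles <- feature_shuffle_surrogate(decoder, n_shuffles,
                                          seed = seed + 1000L + rep_i)
    res <- evaluate_fold(decoder, design_te, kin_te, shuffles)
    res <- cbind(repeat_id = rep_i, res)

    if (n_temporal > 0) {
      pred_act <- predict_hierarchical(decoder, design_te)
      for (ts in seq_len(n_temporal)) {
        kin_sur <- temporal_surrogate(kin_tr, seed = seed + 2000L +
                                        rep_i * 100L + ts)
        dec_sur <- train_hierarchical_decoder(design_tr, kin_sur, cv_folds,
                                              max_comp)
        # Per the surrogate design, the actual classifier gates the
        # surrogate PLS models and the actual predicted speed modulates
        # their velocity; only the regression weights are surrogate.
        dec_sur$classifier <- decoder$classifier
        dec_sur$best_lags <- decoder$best_lags
        sur <- evaluate_fold(dec_sur, design_te, kin_te,
                             speed_override = pred_act$speed)
        sur$condition <- "temporal-surrogate"
        sur$shuffle <- ts
        res <- rbind(res, cbind(repeat_id = rep_i, sur))
      }
    }
    out[[rep_i]] <- res
  }
  do.call(rbind, out)
}

#' Cross-condition (cross-arm) prediction
#'
#' Applies a decoder trained on one dataset to the decode frames of
#' another, with all training lags maintained; the feature layouts must be
#' identical (same channels, features and lag grid).
#'
#' @param decoder a `hierarchical_decoder` trained on arm A.
#' @param prep_b prepared decoding data of arm B.
#' @param test_trials trial ids of arm B to evaluate on (default: all).
#' @param shuffles weight-block permutations for surrogate cross
#'   predictions.
#' @return accuracy table rows as from [evaluate_fold()].
#' @export
cross_predict <- function(decoder, prep_b, test_trials = NULL,
                          shuffles = list()) {
  if (ncol(prep_b$design) != nrow(decoder$pls_move$coef[, , 1])) {
    stop("feature layouts differ between arms", call. = FALSE)
  }
  rows <- if (is.null(test_trials)) rep(TRUE, nrow(prep_b$design)) else
    prep_b$trial_ids %in% test_trials
  design <- prep_b$design[rows, , drop = FALSE]
  kin <- prep_b$kin[rows, , drop = FALSE]
  evaluate_fold(decoder, design, kin, shuffles)
}
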