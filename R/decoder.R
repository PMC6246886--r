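#' Train the hierarchical movement/rest-switched PLS decoder
#'
#' Trains (i) an elastic-net logistic classifier separating movement from
#' rest frames on best-lag features, (ii) a PLS regression on movement
#' frames, and (iii) a PLS regression on rest frames, each predicting
#' speed and the three velocity components from the full lagged design.
#' At prediction time the classifier output switches between the two PLS
#' models and the predicted velocity vector is renormalized to the
#' predicted speed.
#'
#' @param design lagged design matrix over the training frames (from
#'   [build_lagged_design()], rows subset to training frames).
#' @param kin data.frame of frame kinematics aligned to the design rows;
#'   needs columns `speed`, `vx`, `vy`, `vz`, `movement`, `trial_id`.
#' @param cv_folds fold count for all internal cross-validation.
#' @param max_comp largest PLS component count examined.
#' @param lag_ms lag grid (used for best-lag bookkeeping).
#' @return object of class `hierarchical_decoder`.
#' @export
train_hierarchical_decoder <- function(design, kin, cv_folds = 7L,
                                       max_comp = 10L,
                                       lag_ms = lag_grid_ms()) {
  stopifnot(nrow(design) == nrow(kin))
  Y <- as.matrix(kin[, c("speed", "vx", "vy", "vz")])
  move <- as.logical(kin$movement)
  trial_of_row <- kin$trial_id
  fold_id <- fold_by_trial(trial_of_row, cv_folds)

  best_lags <- select_best_lags(design, kin$speed, lag_ms)
  Xb <- design[, best_lags$column, drop = FALSE]
  classifier <- train_movement_classifier(Xb, move, fold_id)

  pls_move <- train_pls(design[move, , drop = FALSE],
                        Y[move, , drop = FALSE],
                        fold_id[move], max_comp)
  pls_rest <- train_pls(design[!move, , drop = FALSE],
                        Y[!move, , drop = FALSE],
                        fold_id[!move], max_comp)

  structure(list(
    classifier = classifier, best_lags = best_lags,
    pls_move = pls_move, pls_rest = pls_rest,
    layout = attr(design, "layout"), lag_ms = lag_ms,
    n_lags = length(lag_ms)
  ), class = "hierarchical_decoder")
}

# Deterministic round-robin fold assignment over whole trials (trials are
# never split across folds).
fold_by_trial <- function(trial_id, n_folds) {
  trials <- unique(trial_id)
  fold_of_trial <- setNames(rep(seq_len(n_folds), length.out =
                                  length(trials)), trials)
  as.integer(fold_of_trial[as.character(trial_id)])
}

#' Predict kinematics with the hierarchical decoder
#'
#' Per frame the classifier selects the movement or rest PLS model; the
#' selected model's raw velocity is scaled to unit norm and multiplied by
#' the (clamped nonnegative) predicted speed, enforcing that the predicted
#' velocity magnitude equals the predicted speed. Weight permutations for
#' surrogate predictions can be supplied: per the surrogate design, the
#' actual classifier gating and the actual model's speed prediction are
#' retained while the shuffled weights produce the velocity direction and
#' the surrogate speed series.
#'
#' @param decoder a `hierarchical_decoder`.
#' @param design lagged design matrix of the frames to predict.
#' @param block_perm optional permutation of the (channel, feature) weight
#'   blocks (see [feature_shuffle_surrogate()]); `NULL` for the actual
#'   model.
#' @param speed_override optional per-frame speed series used to modulate
#'   the velocity direction instead of this model's own prediction (the
#'   surrogate evaluation passes the actual model's predicted speed here).
#' @return data.frame per frame: `state` ("move"/"rest"), `prob_move`,
#'   `speed`, `vx`, `vy`, `vz` (renormalized velocity) and `speed_raw`
#'   (the gated PLS speed before clamping).
#' @export
predict_hierarchical <- function(decoder, design, block_perm = NULL,
                                 speed_override = NULL) {
  stopifnot(inherits(decoder, "hierarchical_decoder"))
  Xb <- design[, decoder$best_lags$column, drop = FALSE]
  prob <- predict(decoder$classifier, Xb)
  move_state <- prob > 0.5

  pred_move <- pls_predict_permuted(decoder$pls_move, design,
                                    decoder$n_lags, block_perm)
  pred_rest <- pls_predict_permuted(decoder$pls_rest, design,
                                    decoder$n_lags, block_perm)
  raw <- pred_rest
  raw[move_state, ] <- pred_move[move_state, ]

  speed_raw <- raw[, 1]
  speed <- pmax(speed_raw, 0)
  modulator <- if (is.null(speed_override)) speed else pmax(speed_override, 0)
  vel <- raw[, 2:4, drop = FALSE]
  nv <- sqrt(rowSums(vel^2))
  scale <- ifelse(nv > 0, modulator / nv, 0)
  vel <- vel * scale
  data.frame(state = ifelse(move_state, "move", "rest"), prob_move = prob,
             speed = speed, speed_raw = speed_raw,
             vx = vel[, 1], vy = vel[, 2], vz = vel[, 3])
}

# Predict from a simpls_fit whose weight rows are permuted across
# (channel, feature) blocks of `n_lags` contiguous rows; block_perm = NULL
# or the identity reproduces the actual model.
pls_predict_permuted <- function(fit, design, n_lags, block_perm = NULL) {
  B <- fit$coef[, , fit$ncomp]
  xm <- fit$x_means
  if (!is.null(block_perm)) {
    n_blocks <- nrow(B) / n_lags
    stopifnot(length(block_perm) == n_blocks)
    row_idx <- as.vector(outer(seq_len(n_lags),
                               (block_perm - 1L) * n_lags, "+"))
    B <- B[row_idx, , drop = FALSE]
  }
  out <- as.matrix(design) %*% B
  offset <- fit$y_means - drop(crossprod(B, xm))
  out + rep(offset, each = nrow(out))
}

#' Integrate predicted velocities into a trajectory
#'
#' Cumulative sum of the velocity vectors times the frame step, starting
#' from the origin (displacement relative to the trial start).
#'
#' @param vel frames x 3 velocity matrix of one trial.
#' @param step_s frame step in seconds.
#' @return frames x 3 matrix of displacements.
#' @export
integrate_trajectory <- function(vel, step_s = 0.05) {
  apply(as.matrix(vel) * step_s, 2, cumsum)
}

#' Percentage of trials whose predicted trajectory ends in the correct octant
#'
#' A trial counts as hit when the sign pattern of the predicted endpoint
#' displacement matches the actual endpoint displacement in all three
#' axes (the 3D generalization of "ending in the same quadrant"; chance
#' for 8 balanced targets is 12.5%).
#'
#' @param actual_disp trials x 3 matrix of actual endpoint displacements.
#' @param pred_disp trials x 3 matrix of predicted endpoint displacements.
#' @return percentage in `[0, 100]`.
#' @export
score_targets_hit <- function(actual_disp, pred_disp) {
  actual_disp <- as.matrix(actual_disp); pred_disp <- as.matrix(pred_disp)
  stopifnot(identical(dim(actual_disp), dim(pred_disp)))
  hits <- rowSums(sign(actual_disp) == sign(pred_disp)) == 3
  100 * mean(hits)
}
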