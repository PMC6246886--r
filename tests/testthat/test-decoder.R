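# Lagged design, lag selection, PLS core, classifier, hierarchical decoder.

test_that("lagged design has the documented layout and shift semantics", {
  nw <- 120
  vals <- array(rnorm(nw * 1 * 8), c(nw, 1, 8))
  feats <- toy_feature_tensor(vals)
  X <- build_lagged_design(feats, 30:90)
  expect_equal(ncol(X), 1 * 8 * 31) # 248 columns
  expect_equal(nrow(X), 61)

  # Constant feature series gives constant columns.
  vals2 <- vals
  vals2[, 1, 2] <- 5
  X2 <- build_lagged_design(toy_feature_tensor(vals2), 30:90)
  lay <- attr(X2, "layout")
  expect_true(all(X2[, lay$feature == 2] == 5))

  # Delta pulse at window 40 appears at frame 50 in the -500 ms column.
  vals3 <- array(0, c(nw, 1, 8))
  vals3[40, 1, 1] <- 1
  X3 <- build_lagged_design(toy_feature_tensor(vals3), 21:100)
  frames <- attr(X3, "frames")
  col <- which(lay$feature == 1 & lay$lag_ms == -500)
  expect_equal(frames[X3[, col] == 1], 50)

  # Frames without full lag coverage are dropped and reported.
  X4 <- build_lagged_design(feats, 1:120)
  expect_equal(attr(X4, "n_dropped"), 120 - nrow(X4))
  expect_true(all(attr(X4, "frames") + 10 <= nw))
  expect_true(all(attr(X4, "frames") - 20 >= 1))
})

test_that("best-lag selection recovers constructed shifts and uses |r|", {
  set.seed(8)
  nw <- 600
  speed_w <- abs(stats::filter(rnorm(nw + 20), rep(0.2, 5), sides = 2))
  speed_w[is.na(speed_w)] <- 0
  speed_w <- as.numeric(speed_w)[1:nw]
  vals <- array(rnorm(nw * 1 * 8, sd = 1e-3), c(nw, 1, 8))
  # Feature 1 leads speed by 200 ms: feature[w] = speed[w + 4].
  vals[1:(nw - 4), 1, 1] <- speed_w[5:nw]
  # Feature 2 is negated speed at lag 0 (absolute correlation counts).
  vals[, 1, 2] <- -speed_w
  feats <- toy_feature_tensor(vals)
  X <- build_lagged_design(feats, 21:(nw - 10))
  sp <- speed_w[attr(X, "frames")]
  bl <- select_best_lags(X, sp)
  expect_equal(bl$lag_ms[bl$feature == 1], -200)
  expect_equal(bl$lag_ms[bl$feature == 2], 0)
  expect_gt(bl$abs_r[bl$feature == 2], 0.99)
  # White-noise features end up with weak correlations at their best lag.
  expect_true(all(bl$abs_r[bl$feature >= 3] < 0.2))
})

test_that("SIMPLS recovers exact linear structure and matches the reference on one response", {
  set.seed(9)
  n <- 300; p <- 40
  # Orthonormalized predictors: with a noiseless 3-column target, three
  # latent components must give an exact fit.
  X0 <- matrix(rnorm(n * p), n, p)
  X <- qr.Q(qr(scale(X0, scale = FALSE))) * sqrt(n - 1)
  C <- matrix(rnorm(3 * 4), 3, 4)
  Y <- X[, c(3, 11, 25)] %*% C
  fit <- simpls_fit(X, Y, 3)
  pred <- predict(fit, X)
  for (j in 1:4) expect_gt(cor(pred[, j], Y[, j]), 0.999)

  # Rank-1 target structure: the second component adds nothing.
  Y1 <- X[, 5, drop = FALSE] %*% matrix(c(1, 2, 3, 4), 1)
  f1 <- simpls_fit(X, Y1, 1)
  f2 <- simpls_fit(X, Y1, 2)
  expect_equal(predict(f1, X), predict(f2, X, ncomp = 2), tolerance = 1e-6)

  # Single-response PLS agrees with the independent reference
  # implementation (mixOmics) where the algorithms coincide.
  skip_if_not_installed("mixOmics")
  X2 <- matrix(rnorm(n * p), n, p)
  colnames(X2) <- paste0("V", seq_len(p))
  y <- X2 %*% rnorm(p) + rnorm(n)
  ours <- predict(simpls_fit(X2, y, 3), X2)
  ref <- mixOmics::pls(X2, y, ncomp = 3, mode = "regression", scale = FALSE)
  ref_pred <- predict(ref, X2)$predict[, 1, 3]
  expect_equal(unname(ours[, 1]), unname(ref_pred), tolerance = 1e-8)
})

test_that("PLS cross-validation is honest under permuted targets", {
  set.seed(10)
  n <- 900; p <- 60
  X <- matrix(rnorm(n * p), n, p)
  Y <- cbind(X %*% rnorm(p, sd = 0.3), X %*% rnorm(p, sd = 0.3))
  fold <- rep(1:7, length.out = n)
  tr <- rep(c(TRUE, FALSE), c(400, 500))
  Yp <- Y[sample(n), ]
  fit <- train_pls(X[tr, ], Yp[tr, ], fold[tr], max_comp = 5)
  pred <- predict(fit, X[!tr, ])
  expect_lt(abs(cor(pred[, 1], Yp[!tr, 1])), 0.15)

  # And recovers signal when it exists.
  fit2 <- train_pls(X[tr, ], Y[tr, ], fold[tr], max_comp = 5)
  pred2 <- predict(fit2, X[!tr, ])
  expect_gt(cor(pred2[, 1], Y[!tr, 1]), 0.9)

  expect_error(train_pls(X[1:3, ], Y[1:3, ], 1:7), "folds")
})

test_that("the movement classifier separates separable data and is honest on noise", {
  set.seed(12)
  n <- 500
  labels <- rep(c(TRUE, FALSE), length.out = n)
  X <- matrix(rnorm(n * 16), n, 16)
  X[labels, 1] <- X[labels, 1] + 6
  fold <- rep(1:7, length.out = n)
  cls <- train_movement_classifier(X, labels, fold)
  acc <- mean((predict(cls, X) > 0.5) == labels)
  expect_gte(acc, 0.95)

  # Labels independent of features: near-chance cross-validated accuracy.
  Xn <- matrix(rnorm(n * 16), n, 16)
  cls_n <- train_movement_classifier(Xn, labels, fold)
  expect_gte(cls_n$cv_error, 0.4)

  # Duplicated columns: regularization keeps predictions stable.
  Xd <- cbind(X, X)
  cls_d <- train_movement_classifier(Xd, labels, fold)
  expect_gt(cor(predict(cls, X), predict(cls_d, Xd)), 0.9)

  expect_error(train_movement_classifier(X, rep(TRUE, n), fold), "single")
})

test_that("hierarchical prediction renormalizes velocity to predicted speed", {
  prep <- small_prep()
  kin <- prep$kin
  design <- prep$design
  decoder <- cached("decoder_small", {
    train_hierarchical_decoder(design, kin, cv_folds = 7, max_comp = 6)
  })
  pred <- predict_hierarchical(decoder, design)
  nv <- sqrt(pred$vx^2 + pred$vy^2 + pred$vz^2)
  pos <- pred$speed > 0
  expect_lt(max(abs(nv[pos] - pred$speed[pos])), 1e-10)
  expect_true(all(nv[!pos] == 0))
  expect_true(all(pred$speed >= 0))

  # Switching contract: rest frames equal the renormalized rest-model
  # output.
  rest_raw <- reachdecode:::pls_predict_permuted(decoder$pls_rest, design,
                                                 decoder$n_lags)
  i <- which(pred$state == "rest")[1:50]
  sp_r <- pmax(rest_raw[i, 1], 0)
  nr <- sqrt(rowSums(rest_raw[i, 2:4]^2))
  expect_equal(pred$vx[i], rest_raw[i, 2] / nr * sp_r, tolerance = 1e-10)

  # Identity weight-block permutation reproduces the actual prediction.
  n_blocks <- ncol(design) / decoder$n_lags
  pred_id <- predict_hierarchical(decoder, design,
                                  block_perm = seq_len(n_blocks))
  expect_equal(pred$speed_raw, pred_id$speed_raw, tolerance = 1e-12)
})

test_that("trajectory integration and octant scoring behave as specified", {
  vel <- matrix(0.1, 10, 3)
  traj <- integrate_trajectory(vel, step_s = 0.05)
  expect_equal(unname(traj[10, ]), c(0.05, 0.05, 0.05))

  act <- matrix(c(1, 1, 1, -1, 1, -1), 2, 3, byrow = TRUE)
  expect_equal(score_targets_hit(act, act), 100)
  expect_equal(score_targets_hit(act, -act), 0)

  # Random octants hit at the 12.5% chance rate.
  set.seed(13)
  a <- matrix(sample(c(-1, 1), 3 * 4000, replace = TRUE), ncol = 3)
  b <- matrix(sample(c(-1, 1), 3 * 4000, replace = TRUE), ncol = 3)
  expect_equal(score_targets_hit(a, b), 12.5, tolerance = 2)
})
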