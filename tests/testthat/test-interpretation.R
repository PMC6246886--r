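# Activation patterns, importance, topography, movement-related stats.

# Whiten columns so the sample covariance is exactly the identity.
whiten <- function(Z) {
  Zc <- scale(Z, scale = FALSE)
  S <- cov(Zc)
  W <- solve(chol(S))
  Zc %*% W
}

test_that("activation pattern equals the weights under identity covariances", {
  set.seed(18)
  n <- 200
  X <- whiten(matrix(rnorm(n * 6), n, 6))
  S <- whiten(matrix(rnorm(n * 2), n, 2))
  W <- matrix(rnorm(6 * 2), 6, 2)
  A <- compute_activation_patterns(W, X, S)
  expect_equal(A, W, tolerance = 1e-8)
})

test_that("the forward-model pattern is recovered from discriminative weights", {
  # Across simulated forward models X = s a' + noise, the transform
  # applied to least-squares weights recovers |a|.
  set.seed(19)
  cors <- replicate(20, {
    n <- 400; p <- 30
    a <- rnorm(p)
    s <- rnorm(n)
    X <- s %*% t(a) + matrix(rnorm(n * p, sd = 0.8), n, p)
    w <- qr.solve(crossprod(X) + 1e-8 * diag(p), crossprod(X, s))
    s_hat <- X %*% w
    A <- compute_activation_patterns(w, X, s_hat)
    cor(abs(A), abs(a))
  })
  expect_gt(median(cors), 0.9)

  # Rescaling the features leaves normalized summaries unchanged.
  set.seed(20)
  n <- 300; p <- 12
  a <- rnorm(p); s <- rnorm(n)
  X <- s %*% t(a) + matrix(rnorm(n * p, sd = 0.5), n, p)
  w <- qr.solve(crossprod(X) + 1e-8 * diag(p), crossprod(X, s))
  A1 <- compute_activation_patterns(w, X, X %*% w)
  X2 <- 2 * X
  w2 <- qr.solve(crossprod(X2) + 1e-8 * diag(p), crossprod(X2, s))
  A2 <- compute_activation_patterns(w2, X2, X2 %*% w2)
  expect_gt(abs(cor(abs(A1), abs(A2))), 0.999)
})

test_that("top-fraction selection counts, ties, and dominance behave", {
  a <- seq_len(100)
  sel <- select_top_fraction(a, 0.25)
  expect_length(sel, 25)
  expect_setequal(sel, 76:100)

  ties <- rep(1, 20)
  expect_equal(select_top_fraction(ties, 0.25), 1:5)

  b <- c(rep(0.01, 99), 10)
  for (f in c(0.01, 0.1, 0.5)) {
    expect_true(100 %in% select_top_fraction(b, f))
  }
  expect_error(select_top_fraction(numeric(0)), "empty")
  expect_error(select_top_fraction(a, 0), "fraction")
})

test_that("importance shares normalize over the selected set", {
  layout <- data.frame(
    channel = rep(1:4, each = 8 * 3),
    feature = rep(rep(1:8, each = 3), 4),
    lag_ms = rep(c(-100, -50, 0), 32)
  )
  A <- numeric(nrow(layout))
  A[layout$channel == 2] <- 1 # single active channel
  sel <- select_top_fraction(A, 0.25)
  imp <- summarize_importance(A, layout, sel)
  expect_equal(imp$channel_share[2], 1)
  expect_equal(sum(imp$channel_share), 1)
  expect_equal(sum(imp$feature_share), 1)

  set.seed(21)
  A2 <- abs(rnorm(nrow(layout)))
  sel2 <- select_top_fraction(A2, 0.25)
  imp2 <- summarize_importance(A2, layout, sel2)
  expect_equal(sum(imp2$channel_share), 1, tolerance = 1e-12)
  expect_true(all(imp2$channel_score >= 0 & imp2$channel_score <= 1))
  # Peak lags come from the lag grid.
  expect_true(all(imp2$peak_lags$lag_ms %in% c(-100, -50, 0)))
})

test_that("cross-arm pattern correlation uses absolute values", {
  set.seed(22)
  a <- rnorm(500)
  expect_equal(compare_arm_patterns(a, a)$r, 1)
  expect_equal(compare_arm_patterns(a, -a)$r, 1)
  b <- rnorm(500)
  expect_lt(abs(compare_arm_patterns(a, b)$r), 0.12)
  expect_error(compare_arm_patterns(a, b[1:10]), "shape")
})

test_that("topography is an exact convex combination of electrode values", {
  coords <- matrix(c(0, 0), 1, 2)
  tp <- project_topography(coords, 3.7, kernel_sd = 1,
                           grid_x = c(-1, 0, 1), grid_y = c(0))
  expect_equal(tp$map[2, 1], 3.7)
  expect_equal(tp$map, matrix(3.7, 3, 1), tolerance = 1e-12)

  coords2 <- rbind(c(-1, 0), c(1, 0))
  tp2 <- project_topography(coords2, c(5, 5), kernel_sd = 0.8,
                            grid_x = seq(-1, 1, by = 0.5), grid_y = 0)
  expect_true(all(abs(tp2$map - 5) < 1e-12))

  set.seed(23)
  coords3 <- matrix(runif(20), 10, 2)
  vals <- rnorm(10)
  tp3 <- project_topography(coords3, vals, kernel_sd = 0.3)
  expect_gte(min(tp3$map), min(vals))
  expect_lte(max(tp3$map), max(vals))
})

test_that("BY step-up matches the hand-computed example and nests inside BH", {
  # Hand-computed: m = 4, c(4) = 25/12, BY thresholds i * 0.05 / (4 * 25/12)
  # = i * 0.006: only p = 0.001 is rejected.
  p <- c(0.001, 0.02, 0.04, 0.5)
  adj <- fdr_adjust(p, "BY")
  expect_equal(sum(adj < 0.05), 1)
  expect_equal(adj, p.adjust(p, "BY"))

  set.seed(24)
  for (i in 1:20) {
    pv <- runif(50)^2
    by_rej <- which(fdr_adjust(pv, "BY") < 0.05)
    bh_rej <- which(fdr_adjust(pv, "BH") < 0.05)
    expect_true(all(by_rej %in% bh_rej))
  }
})

test_that("movement-related stats flag real effects and stay quiet under the null", {
  set.seed(25)
  dims <- c(20, 6, 4, 3) # trials x windows x channels x features
  za <- array(rnorm(prod(dims)), dims)
  zb <- array(rnorm(prod(dims)), dims)
  # Strong activation: channel 2, feature 1, windows 3:5, hand A only.
  za[, 3:5, 2, 1] <- za[, 3:5, 2, 1] + 3
  res <- movement_related_stats(list(contra = za, ipsi = zb))
  cells <- res$cells
  hit <- cells[cells$hand == "contra" & cells$channel == 2 &
                 cells$feature == 1 & cells$window %in% 3:5, ]
  expect_true(all(hit$active))
  null_cells <- cells[cells$hand == "ipsi", ]
  expect_lt(mean(null_cells$active), 0.02)
  pa <- res$percent_active
  expect_true(all(pa$percent_active >= 0 & pa$percent_active <= 100))
  # The between-hand contrast flags the differing cells.
  btw <- res$between
  expect_true(any(btw$p_adj[btw$channel == 2 & btw$feature == 1] < 0.05))
})

test_that("lagged percent-active correlation finds constructed shifts", {
  set.seed(26)
  base <- stats::filter(rnorm(80), rep(0.4, 6), circular = TRUE)
  base <- as.numeric(base)
  out <- active_timecourse_lag(base, base)
  expect_equal(out$lag_ms, 0)
  expect_equal(out$r, 1)

  shifted <- c(base[79:80], base[1:78]) # curve B = A delayed 100 ms
  out2 <- active_timecourse_lag(base[1:60], shifted[1:60])
  expect_lte(abs(out2$lag_ms - 100), 50)

  a <- rnorm(60); b <- rnorm(60)
  expect_lt(active_timecourse_lag(a, b)$r, 0.5)
  expect_error(active_timecourse_lag(rep(1, 60), rep(1, 60)), "constant")
})
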