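# Splits, surrogate constructions, fold evaluation, rank-sum harness.

test_that("trial splits are disjoint, exhaustive, and reproducible", {
  ids <- 1:80
  splits <- make_splits(ids, n_repeats = 10, seed = 3)
  for (sp in splits) {
    expect_length(sp$train, 70)
    expect_length(sp$test, 10)
    expect_setequal(c(sp$train, sp$test), ids)
    expect_length(intersect(sp$train, sp$test), 0)
  }
  again <- make_splits(ids, n_repeats = 10, seed = 3)
  expect_identical(splits, again)
  expect_error(make_splits(1:5, 3), "at least 8")
  expect_error(make_splits(ids, 3, train_frac = 1), "test set")
})

test_that("the temporal surrogate preserves per-trial value multisets and autocorrelation", {
  set.seed(14)
  n_tr <- 12; n_fr <- 60
  kin <- data.frame(
    trial_id = rep(1:n_tr, each = n_fr),
    speed = abs(as.numeric(replicate(n_tr, {
      s <- stats::filter(rnorm(n_fr), rep(0.3, 8), circular = TRUE)
      as.numeric(s)
    }))),
    vx = rnorm(n_tr * n_fr), vy = rnorm(n_tr * n_fr),
    vz = rnorm(n_tr * n_fr), movement = rep(FALSE, n_tr * n_fr)
  )
  sur <- temporal_surrogate(kin, seed = 4)
  expect_identical(sur$trial_id, kin$trial_id)
  # Circular shifting preserves each trial's sorted value multiset (trials
  # here share one length, so slots match sources exactly).
  all_sorted <- function(d) sort(round(d$speed, 12))
  expect_equal(all_sorted(sur), all_sorted(kin))

  lag1 <- function(x) cor(x[-1], x[-length(x)])
  expect_lt(abs(lag1(sur$speed) - lag1(kin$speed)), 0.05)

  # The surrogate is not the identity (alignment is destroyed).
  expect_gt(mean(sur$speed != kin$speed), 0.5)
})

test_that("weight-shuffle surrogates permute blocks and keep determinism", {
  prep <- small_prep()
  decoder <- cached("decoder_small", {
    train_hierarchical_decoder(prep$design, prep$kin, cv_folds = 7,
                               max_comp = 6)
  })
  sh <- feature_shuffle_surrogate(decoder, n_shuffles = 5, seed = 6)
  sh2 <- feature_shuffle_surrogate(decoder, n_shuffles = 5, seed = 6)
  expect_identical(sh, sh2)
  n_blocks <- ncol(prep$design) / decoder$n_lags
  for (p in sh) expect_setequal(p, seq_len(n_blocks))

  # A shuffled weight matrix is a row-block permutation of the original.
  B <- decoder$pls_move$coef[, , decoder$pls_move$ncomp]
  perm <- sh[[1]]
  row_idx <- as.vector(outer(seq_len(decoder$n_lags),
                             (perm - 1L) * decoder$n_lags, "+"))
  Bp <- B[row_idx, ]
  expect_equal(sort(Bp[, 1]), sort(B[, 1]))
})

test_that("fold evaluation scores perfect and inverted predictions correctly", {
  set.seed(15)
  n_tr <- 8; n_fr <- 40
  kin <- data.frame(
    trial_id = rep(1:n_tr, each = n_fr),
    speed = abs(rnorm(n_tr * n_fr)),
    vx = rnorm(n_tr * n_fr), vy = rnorm(n_tr * n_fr), vz = rnorm(n_tr * n_fr)
  )
  pred_perfect <- kin[, c("speed", "vx", "vy", "vz")]
  m <- reachdecode:::prediction_metrics(pred_perfect, kin)
  expect_equal(unname(unlist(m[1, 1:4])), rep(1, 4))
  expect_equal(m$targets_hit, 100)

  pred_neg <- pred_perfect
  pred_neg[, c("vx", "vy", "vz")] <- -pred_neg[, c("vx", "vy", "vz")]
  m2 <- reachdecode:::prediction_metrics(pred_neg, kin)
  expect_equal(unname(unlist(m2[1, 2:4])), rep(-1, 3))
  expect_equal(m2$targets_hit, 0)
})

test_that("rank-sum statistics match exact enumeration and the reference test", {
  rs <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(rs$W, 6)
  expect_equal(rs$p, 0.1)
  expect_equal(rs$method, "exact")

  # Exhaustive agreement with the reference implementation for all group
  # sizes up to 6 (W here is the rank sum: U + n1 (n1 + 1) / 2).
  set.seed(16)
  for (n1 in 2:6) {
    for (n2 in 2:6) {
      x <- rnorm(n1); y <- rnorm(n2)
      ours <- rank_sum_test(x, y)
      ref <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(ours$W - n1 * (n1 + 1) / 2, unname(ref$statistic))
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
    }
  }

  # Large-sample normal approximation tracks the reference with
  # continuity correction.
  x <- rnorm(40); y <- rnorm(45) + 0.5
  ours <- rank_sum_test(x, y)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-6)

  # Identical groups: not significant.
  z <- rep(c(1, 2, 3), 4)
  expect_gt(rank_sum_test(z, z)$p, 0.9)
})

test_that("the Bonferroni family enumerates to 215 comparisons", {
  expect_equal(bonferroni_comparison_count(), 215L)
  expect_equal(signif(bonferroni_critical_p(), 2), 0.00023)
  # Structure: 40 group surrogate + 5 between-hand + 10 true-vs-cross +
  # 160 per-patient comparisons.
  expect_equal(bonferroni_comparison_count(n_patients = 0), 55L)
})

test_that("distribution comparison controls type-I error at the corrected level", {
  cmp <- compare_distributions(c(1, 2, 3, 4), c(1, 2, 3, 4), m = 10)
  expect_false(cmp$significant)
  expect_gt(cmp$p, 0.9)

  # Null calibration of the harness: identical distributions are flagged
  # at no more than the nominal rate.
  set.seed(17)
  hits <- replicate(200, {
    compare_distributions(rnorm(20), rnorm(20), m = 1, alpha = 0.05)$significant
  })
  expect_lte(mean(hits), 0.08)

  expect_error(compare_distributions(1:2, 1:5), "at least 3")
})
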