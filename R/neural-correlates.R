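#' Movement-related feature statistics with FDR control
#'
#' For onset-aligned z-scored feature tensors (one per hand), tests per
#' electrode, feature, time window and hand whether the across-trial mean
#' z-score differs from 0 (one-sample t test), and per electrode, feature
#' and window whether the two hands differ (two-sample t test on absolute
#' z). All p-values are adjusted jointly with Benjamini-Yekutieli FDR
#' correction, which stays valid under the strong dependence created by
#' overlapping analysis windows.
#'
#' @param z_by_hand named list of two arrays `trials x windows x channels
#'   x features` of onset-aligned z-scores (names are the hand labels).
#' @param alpha significance level applied to the adjusted p-values.
#' @return list with `cells` (data.frame per hand/channel/feature/window:
#'   mean z, t, p, p_adj, active flag), `between` (two-sample comparisons
#'   with p_adj), and `percent_active` (data.frame per hand/feature/window).
#' @export
movement_related_stats <- function(z_by_hand, alpha = 0.05) {
  stopifnot(length(z_by_hand) == 2, !is.null(names(z_by_hand)))
  cells <- list()
  for (hand in names(z_by_hand)) {
    z <- z_by_hand[[hand]]
    stopifnot(length(dim(z)) == 4)
    if (dim(z)[1] < 2) stop("need at least 2 trials per hand", call. = FALSE)
    nt <- dim(z)[1]
    mu <- apply(z, c(2, 3, 4), mean)
    sdv <- apply(z, c(2, 3, 4), sd)
    tval <- mu / (sdv / sqrt(nt))
    p <- 2 * pt(-abs(tval), df = nt - 1)
    grid <- expand.grid(window = seq_len(dim(z)[2]),
                        channel = seq_len(dim(z)[3]),
                        feature = seq_len(dim(z)[4]))
    cells[[hand]] <- data.frame(hand = hand, grid, mean_z = as.numeric(mu),
                                t = as.numeric(tval), p = as.numeric(p))
  }
  cells <- do.call(rbind, cells)
  # Degenerate cells (zero across-trial variance) are flagged and excluded
  # from the correction.
  cells$degenerate <- !is.finite(cells$t)
  hands <- names(z_by_hand)
  za <- z_by_hand[[1]]; zb <- z_by_hand[[2]]
  stopifnot(identical(dim(za)[-1], dim(zb)[-1]))
  dims <- dim(za)[-1]
  grid <- expand.grid(window = seq_len(dims[1]), channel = seq_len(dims[2]),
                      feature = seq_len(dims[3]))
  between_p <- numeric(nrow(grid))
  between_t <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    a <- abs(za[, grid$window[i], grid$channel[i], grid$feature[i]])
    b <- abs(zb[, grid$window[i], grid$channel[i], grid$feature[i]])
    if (sd(a) == 0 && sd(b) == 0) {
      between_t[i] <- NA_real_; between_p[i] <- NA_real_
    } else {
      tt <- t.test(a, b)
      between_t[i] <- unname(tt$statistic); between_p[i] <- tt$p.value
    }
  }
  between <- data.frame(grid, t = between_t, p = between_p)

  all_p <- c(cells$p[!cells$degenerate], between$p[!is.na(between$p)])
  adj <- fdr_adjust(all_p, "BY")
  n1 <- sum(!cells$degenerate)
  cells$p_adj <- NA_real_
  cells$p_adj[!cells$degenerate] <- adj[seq_len(n1)]
  between$p_adj <- NA_real_
  between$p_adj[!is.na(between$p)] <- adj[-seq_len(n1)]
  cells$active <- !is.na(cells$p_adj) & cells$p_adj < alpha

  pa <- stats::aggregate(active ~ hand + feature + window, cells,
                         function(v) 100 * mean(v))
  names(pa)[names(pa) == "active"] <- "percent_active"
  list(cells = cells, between = between, percent_active = pa)
}

#' Peak lagged correlation between two percent-active time courses
#'
#' Slides one curve against the other over lags on the frame grid and
#' reports the lag with the peak Pearson correlation over the overlapping
#' span.
#'
#' @param curve_a,curve_b percent-active time courses on the same frame
#'   grid (e.g. contralateral and ipsilateral hands).
#' @param max_lag_frames largest shift examined in frames (default 10,
#'   i.e. +/-500 ms at the 50 ms step).
#' @param step_ms frame step in milliseconds.
#' @return list with `lag_ms`, `r` (at the peak), and `by_lag`
#'   (data.frame of all lags). Positive lags mean `curve_a` leads.
#' @export
active_timecourse_lag <- function(curve_a, curve_b, max_lag_frames = 10L,
                                  step_ms = 50) {
  stopifnot(length(curve_a) == length(curve_b))
  n <- length(curve_a)
  if (n <= max_lag_frames + 2) stop("curves shorter than the lag span",
                                    call. = FALSE)
  lags <- seq(-max_lag_frames, max_lag_frames)
  rs <- vapply(lags, function(l) {
    if (l >= 0) {
      a <- curve_a[seq_len(n - l)]
      b <- curve_b[seq_len(n - l) + l]
    } else {
      a <- curve_a[seq_len(n + l) - l]
      b <- curve_b[seq_len(n + l)]
    }
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }, numeric(1))
  if (all(is.na(rs))) stop("constant curve: correlation undefined",
                           call. = FALSE)
  best <- which.max(rs)
  list(lag_ms = lags[best] * step_ms, r = rs[best],
       by_lag = data.frame(lag_ms = lags * step_ms, r = rs))
}
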