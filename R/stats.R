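#' Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Two-sided rank-sum test reporting the rank-sum statistic `W` (sum of
#' the ranks of the first group in the pooled sample) and a z-statistic.
#' For group sizes both at most `exact_max` the null distribution is
#' enumerated exhaustively (valid under ties); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param exact_max largest group size for which exact enumeration is used.
#' @return list with `W`, `z`, `p`, `method`.
#' @export
rank_sum_test <- function(x, y, exact_max = 10L) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  if (n1 < 1 || n2 < 1) stop("both groups must be nonempty", call. = FALSE)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) {
    (W - mu - 0.5 * sign(W - mu)) / sqrt(sigma2)
  } else 0
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n, n1)
    sums <- colSums(matrix(r[combs], nrow = n1))
    p_lo <- mean(sums <= W)
    p_hi <- mean(sums >= W)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    p <- 2 * pnorm(-abs(z))
    method <- "normal"
  }
  list(W = W, z = z, p = p, method = method)
}

#' Enumerate the Bonferroni comparison family of the analysis plan
#'
#' Counts every planned actual-versus-surrogate, between-hand, and
#' true-versus-cross comparison at the group and individual-patient
#' level: `params x hands x prediction-conditions x surrogates` (group
#' surrogate tests) + `params` (between hands) + `params x hands`
#' (true vs cross) + `patients x params x hands x conditions x surrogates`
#' (per-patient surrogate tests). The default plan (5 kinematic
#' parameters, 2 hands, 2 prediction conditions, 2 surrogate methods,
#' 4 patients) yields 215 comparisons.
#'
#' @param n_params kinematic parameters tested (speed, Vx, Vy, Vz,
#'   targets hit).
#' @param n_hands arms tested.
#' @param n_conditions prediction conditions (true and cross-prediction).
#' @param n_surrogates surrogate constructions.
#' @param n_patients individual datasets.
#' @return integer comparison count.
#' @export
bonferroni_comparison_count <- function(n_params = 5L, n_hands = 2L,
                                        n_conditions = 2L,
                                        n_surrogates = 2L, n_patients = 4L) {
  group_surrogate <- n_params * n_hands * n_conditions * n_surrogates
  between_hands <- n_params
  true_vs_cross <- n_params * n_hands
  per_patient <- n_patients * n_params * n_hands * n_conditions *
    n_surrogates
  as.integer(group_surrogate + between_hands + true_vs_cross + per_patient)
}

#' Bonferroni-corrected critical p-value for the analysis plan
#'
#' @param alpha family-wise error rate.
#' @param m comparison count (default: the full analysis plan).
#' @return corrected per-comparison threshold `alpha / m`.
#' @export
bonferroni_critical_p <- function(alpha = 0.05,
                                  m = bonferroni_comparison_count()) {
  alpha / m
}

#' Compare actual and surrogate accuracy distributions
#'
#' Two-sided rank-sum test with Bonferroni correction over the configured
#' comparison family.
#'
#' @param actual,surrogate numeric accuracy samples.
#' @param m total comparison count in the family.
#' @param alpha family-wise error rate.
#' @return data.frame with medians, `W`, `z`, `p`, the corrected threshold
#'   and a significance flag.
#' @export
compare_distributions <- function(actual, surrogate,
                                  m = bonferroni_comparison_count(),
                                  alpha = 0.05) {
  if (length(actual) < 3 || length(surrogate) < 3) {
    stop("need at least 3 samples per group", call. = FALSE)
  }
  ts <- rank_sum_test(actual, surrogate)
  thr <- alpha / m
  data.frame(median_actual = median(actual),
             median_surrogate = median(surrogate),
             W = ts$W, z = ts$z, p = ts$p, m = m,
             critical_p = thr, significant = ts$p < thr)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence
#' (the overlapping analysis windows make p-values strongly correlated,
#' which is why the conservative variant is the default here).
#'
#' @param p numeric vector of p-values.
#' @param method `"BY"` (default) or `"BH"`.
#' @return adjusted p-values.
#' @export
fdr_adjust <- function(p, method = c("BY", "BH")) {
  method <- match.arg(method)
  p.adjust(p, method = method)
}
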