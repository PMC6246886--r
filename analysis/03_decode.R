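#!/usr/bin/env Rscript

# Stage 3: hierarchical decoding with resampled train/test evaluation.
# Per split: an elastic-net logistic classifier separates movement from
# rest frames; two multivariate PLS regressions over lagged features
# (-1000..500 ms, 50 ms steps) predict speed and velocity in each state;
# the predicted velocity is renormalized to the predicted speed. Weight-
# shuffle surrogates and one temporal-surrogate model per split provide
# the chance reference.
#
# Reads scratch/demo_prep.rds; writes results/demo/accuracy.tsv.

library(reachdecode)

prep <- readRDS("scratch/demo_prep.rds")
cfg <- default_run_config("demo", seed = 7)

accuracy <- run_decoding_evaluation(
  prep,
  n_repeats = cfg$evaluation$n_repeats,
  n_shuffles = cfg$evaluation$n_shuffles,
  n_temporal = cfg$evaluation$n_temporal,
  seed = 9
)
write_report_tsv(accuracy, "results/demo/accuracy.tsv")

act <- accuracy[accuracy$condition == "actual", ]
cat(sprintf("actual (median over %d splits): speed r = %.3f, Vx r = %.3f, Vy r = %.3f, Vz r = %.3f, targets hit = %.1f%%\n",
            nrow(act), median(act$speed_r), median(act$vx_r),
            median(act$vy_r), median(act$vz_r), median(act$targets_hit)))
for (cond in c("feature-surrogate", "temporal-surrogate")) {
  sur <- accuracy[accuracy$condition == cond, ]
  if (nrow(sur) == 0) next
  cat(sprintf("%s: speed r = %.3f, mean velocity r = %.3f, targets hit = %.1f%%\n",
              cond, median(sur$speed_r),
              mean(c(sur$vx_r, sur$vy_r, sur$vz_r)),
              mean(sur$targets_hit)))
}
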