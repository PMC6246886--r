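#!/usr/bin/env Rscript

# Stage 4: statistical comparison of actual vs surrogate accuracies with
# the rank-sum test and Bonferroni correction over the full comparison
# family of the analysis plan (5 kinematic parameters x 2 hands x 2
# prediction conditions x 2 surrogate methods at the group level, plus
# between-hand, true-vs-cross, and per-patient comparisons: m = 215,
# critical p = 0.00023).
#
# Reads results/demo/accuracy.tsv; writes results/demo/stat_report.tsv.

library(reachdecode)

accuracy <- utils::read.delim("results/demo/accuracy.tsv")
report <- summarize_accuracy_stats(accuracy)
write_report_tsv(report, "results/demo/stat_report.tsv")

cat(sprintf("comparison family: m = %d, corrected critical p = %.5f\n",
            bonferroni_comparison_count(), bonferroni_critical_p()))
print(report[, c("metric", "condition", "median_actual",
                 "median_surrogate", "W", "z", "p", "significant")],
      digits = 3)
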