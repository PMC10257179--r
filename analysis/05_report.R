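#!/usr/bin/env Rscript
# Stage 5: decision tables.
#
# Per-experiment rank-sum comparisons (median + range + two-sided p against
# the matched control) and the ranked efficacy table: posterior median effect,
# 95% credible interval and Pr(efficacy) for the concurrent and pooled
# analyses side by side, sorted by pooled Pr(efficacy).

library(poolctrl)

trial <- read_trial_csv("results/trial_final.csv")

comparisons <- group_comparisons(trial)
utils::write.csv(comparisons, "results/group_comparisons.csv", row.names = FALSE)
cat("Per-experiment rank-sum comparisons:\n")
print(comparisons[order(comparisons$p_value),
                  c("experiment_id", "treatment", "control_median",
                    "treatment_median", "p_value")],
      digits = 3)

fit <- fit_pooled(trial, mcmc = mcmc_config(4, 10000, 5000, seed = 2026))
concurrent <- lapply(sort(unique(trial$experiment_id)), function(e) {
  fit_concurrent(trial, e, mcmc = mcmc_config(4, 10000, 5000, seed = 2026))
})

report <- build_report(fit, concurrent)
utils::write.csv(as.data.frame(report), "results/efficacy_report.csv",
                 row.names = FALSE)
if (requireNamespace("jsonlite", quietly = TRUE)) {
  jsonlite::write_json(as.data.frame(report), "results/efficacy_report.json",
                       auto_unbox = TRUE, digits = NA)
}

cat("\n")
print(report)
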