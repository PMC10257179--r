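#!/usr/bin/env Rscript
# Stage 2: moderate-injury quality gate.
#
# Experiments whose control-group median area loss falls outside [35, 50]%
# do not represent the moderate-injury phenotype the model targets; they are
# removed with all their arms. Writes the per-experiment verdict table and
# the filtered dataset.

library(poolctrl)

trial <- read_trial_csv("results/trial_simulated.csv")
qc <- qc_filter(trial)

utils::write.csv(qc$report, "results/qc_report.csv", row.names = FALSE)
utils::write.csv(as.data.frame(qc$dataset), "results/trial_qc.csv",
                 row.names = FALSE)

print(qc$report)
cat(sprintf("\nRetained %d of %d experiments (%d animals).\n",
            sum(qc$report$verdict == "retained"), nrow(qc$report),
            nrow(qc$dataset)))
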