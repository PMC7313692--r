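#!/usr/bin/env Rscript
# Step 3: relate the epoch EEG parameters to the CBF recovery rates:
# Pearson correlations for all eleven parameters, quartile-group ANOVA
# with Dunnett T3 post hoc comparisons, and median-split ROC analysis
# with Youden cut-offs for the leading parameters. Tables land in
# results/ (correlations.csv, anova_posthoc.csv, roc.csv).

suppressMessages(library(cpreeg))

if (!file.exists("results/features.csv"))
  stop("no feature table found; run analysis/02_extract_features.R first")

features <- utils::read.csv("results/features.csv")
epochs <- utils::read.csv("results/epochs.csv")

recovery <- assign_recovery_groups(epochs$value_pct)
report <- build_report(features, recovery, out_dir = "results")

print(report)
cat("\ngroup sizes (quartiles of CBF recovery):",
    unlist(report$log$group_sizes), "\n")
cat("report tables written under results/\n")
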