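#!/usr/bin/env Rscript
# Step 2: load the simulated recordings from results/data/, extract the
# 3-s pre-defibrillation pause epochs, compute the eleven EEG parameters
# per epoch (three-sub-epoch averaging) and the paired CBF recovery
# rates, and write results/features.csv + results/epochs.csv.

suppressMessages(library(cpreeg))

data_dir <- "results/data"
if (!dir.exists(data_dir))
  stop("no simulated data found; run analysis/01_simulate_cohort.R first")

subjects <- sub("_data\\.csv$", "",
                basename(list.files(data_dir, pattern = "_data\\.csv$")))
paths <- lapply(subjects, function(s) list(
  data = file.path(data_dir, paste0(s, "_data.csv")),
  events = file.path(data_dir, paste0(s, "_events.csv"))))

res <- run_pipeline(run_config(mode = "load", paths = paths,
                               out_dir = "results"))

cat(sprintf("extracted %d pre-defibrillation epochs from %d subjects\n",
            res$log$n_epochs, res$log$n_subjects))
cat(sprintf("dropped epochs (insufficient history): %d\n", res$log$dropped_epochs))
cat(sprintf("epoch CBF recovery: median %.1f%%, range %.1f-%.1f%% of baseline\n",
            res$log$median_split_pct, min(res$epochs$value_pct),
            max(res$epochs$value_pct)))
cat("feature table written to results/features.csv\n")
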