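#!/usr/bin/env Rscript

# Step 2: extract the workload metrics.
#
# Reads every recording set in scratch/study/ and computes the full
# metric battery per participant x condition: pupil L1NS / STDP / LPF
# per eye, gaze NNI / fixation rate / saccade rate / median SI velocity,
# EEG band-power medians (theta, alpha, low beta, high beta), and
# inceptor duty cycle / aggressiveness plus altitude and airspeed %RMSE.
# Writes the long-form metric table to results/metrics.csv and the
# per-condition PIW points to results/piw.csv.

suppressPackageStartupMessages(library(cogload))

study_dir <- "scratch/study"
if (!dir.exists(study_dir)) {
  stop("no study at ", study_dir, "; run analysis/01_simulate_study.R first")
}
dir.create("results", showWarnings = FALSE)

mt <- extract_metrics(study_dir)
utils::write.csv(mt, "results/metrics.csv", row.names = FALSE)

# PIW table: aggressiveness vs duty cycle per recording
wide <- merge(
  mt[mt$metric == "aggressiveness", c("participant", "condition", "value")],
  mt[mt$metric == "duty_cycle", c("participant", "condition", "value")],
  by = c("participant", "condition"), suffixes = c("_aggr", "_dc"))
names(wide)[3:4] <- c("aggressiveness", "duty_cycle")
utils::write.csv(wide, "results/piw.csv", row.names = FALSE)

cat(sprintf("Extracted %d metric values (%d metrics x %d recordings)\n",
            nrow(mt), length(unique(mt$metric)),
            nrow(unique(mt[c("participant", "condition")]))))
for (cond in unique(wide$condition)) {
  sub <- wide[wide$condition == cond, ]
  cat(sprintf("  %s: mean DC %.1f%%, mean aggressiveness %.2f (mm/s)^2\n",
              cond, mean(sub$duty_cycle), mean(sub$aggressiveness)))
}
cat("Tables written to results/metrics.csv and results/piw.csv\n")
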