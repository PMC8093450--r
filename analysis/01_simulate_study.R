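#!/usr/bin/env Rscript

# Step 1: simulate the study.
#
# Generates the default synthetic repeated-measures study -- 12
# participants flying three task conditions (C1 baseline take-off/climb,
# C2 with an altitude-holding constraint, C3 with an added secondary
# task) -- and writes one CSV recording set per participant x condition
# under scratch/study/, plus a manifest.json with every true generating
# parameter. Later steps read only those CSVs, exactly as they would a
# real study export.

suppressPackageStartupMessages(library(cogload))

seed <- 20260919 %% 100000
out <- "scratch/study"

cfg <- study_config(seed = seed)
st <- gen_study(cfg, out_dir = out, force = TRUE)

cat("Simulated study written to", out, "\n")
cat(sprintf("  participants: %d, conditions: %s (workloads %s)\n",
            cfg$participants,
            paste(cfg$conditions$name, collapse = "/"),
            paste(cfg$conditions$workload, collapse = "/")))
cat(sprintf("  recording sets: %d (%d files + manifest)\n",
            cfg$participants * nrow(cfg$conditions),
            length(list.files(out, recursive = TRUE)) - 1))
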