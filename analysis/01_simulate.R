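#!/usr/bin/env Rscript
# Stage 1 — simulate the two landing series.
#
# Generates one series of 52 single-leg landings per surface condition
# (SG: stable ground, UG: unstable ground) with a known three-synergy
# ground truth, and writes each trial as a directory of CSV streams plus a
# JSON sidecar under results/trials/<condition>/.
#
# Usage: Rscript analysis/01_simulate.R [seed]

suppressPackageStartupMessages(library(landsyn))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1L]]) else 20260101L

set.seed(seed)
cond_seeds <- sample.int(.Machine$integer.max - 2L, 2L)

for (i in seq_along(conds <- c("SG", "UG"))) {
  cond <- conds[i]
  trials <- synthesize_cohort(52L, cond, seed = cond_seeds[i],
                              bodyweight = 660, noise_snr = 20)
  dir <- file.path("results", "trials", cond)
  write_trials(trials, dir)
  cat(sprintf("%s: %d trials -> %s\n", cond, length(trials), dir))
}
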