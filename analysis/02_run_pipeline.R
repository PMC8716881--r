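#!/usr/bin/env Rscript
# Stage 2 — condition, segment, extract and classify.
#
# Reads the simulated trials written by 01_simulate.R, drops the first and
# last landing of each series, conditions and amplitude-normalizes the EMG
# (reference maxima from the stable-ground series), segments on the
# vertical ground reaction force, extracts muscle synergies per trial,
# classifies them per condition, and writes the full artifact tree
# (metric and classification tables, centroids, summary.json) to
# results/run/.
#
# Usage: Rscript analysis/02_run_pipeline.R [seed]

suppressPackageStartupMessages(library(landsyn))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1L]]) else 20260101L

trials <- list(SG = read_trials(file.path("results", "trials", "SG")),
               UG = read_trials(file.path("results", "trials", "UG")))

cfg <- pipeline_config(seed = seed, out_dir = file.path("results", "run"))
res <- run_pipeline(cfg, trials = trials)

cat(sprintf("analyzed %d SG + %d UG trials (%d quarantined)\n",
            res$summary$n_trials[["SG"]], res$summary$n_trials[["UG"]],
            sum(res$quarantined)))
cat(sprintf("clusters: SG k=%d, UG k=%d; artifacts in %s\n",
            res$summary$k[["SG"]], res$summary$k[["UG"]], cfg$out_dir))
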