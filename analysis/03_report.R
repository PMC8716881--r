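#!/usr/bin/env Rscript
# Stage 3 — condition comparison report.
#
# Reads the artifact tree written by 02_run_pipeline.R and summarizes the
# stable- vs unstable-ground comparison: synergy counts, cluster widths
# (FWHM) and centers of activation (CoA) per functional cluster,
# co-activation indices per joint, and the CoP 95 % ellipse areas.  Writes
# a plain-markdown report to results/report.md.
#
# Usage: Rscript analysis/03_report.R

run_dir <- file.path("results", "run")
metrics <- read.csv(file.path(run_dir, "synergy_metrics.csv"))
cop <- read.csv(file.path(run_dir, "cop_areas.csv"))
summ <- jsonlite::read_json(file.path(run_dir, "summary.json"),
                            simplifyVector = TRUE)

cls <- lapply(c(SG = "SG", UG = "UG"), function(cond)
  read.csv(file.path(run_dir, sprintf("classification_%s.csv", cond))))

fmt <- function(x, d = 2) formatC(x, format = "f", digits = d)

lines <- c("# Landing synergy analysis — condition comparison", "")
lines <- c(lines, sprintf(
  "Seed %s; %s SG and %s UG trials analyzed, %s quarantined.",
  summ$seed, summ$n_trials[["SG"]], summ$n_trials[["UG"]],
  sum(unlist(summ$quarantined))), "")

lines <- c(lines, "## Synergy structure", "",
           "| condition | k | mean rank | fundamental fraction |",
           "|---|---|---|---|")
for (cond in c("SG", "UG")) {
  lines <- c(lines, sprintf("| %s | %s | %s | %s |", cond, summ$k[[cond]],
                            fmt(summ$mean_rank[[cond]]),
                            fmt(summ$fundamental_fraction[[cond]])))
}

lines <- c(lines, "", "## Cluster timing (pooled primitives)", "",
           "| condition | cluster | n | mean FWHM (pts) | mean CoA (pts) |",
           "|---|---|---|---|---|")
for (cond in c("SG", "UG")) {
  tab <- cls[[cond]]
  for (nm in unique(tab$functional_name)) {
    sub <- merge(tab[tab$functional_name == nm, c("trial", "synergy")],
                 metrics[metrics$condition == cond, ])
    lines <- c(lines, sprintf("| %s | %s | %d | %s | %s |", cond, nm,
                              nrow(sub), fmt(mean(sub$fwhm), 1),
                              fmt(mean(sub$coa), 1)))
  }
}

lines <- c(lines, "", "## Co-activation index (mean over synergies)", "",
           "| condition | hip | knee | ankle |", "|---|---|---|---|")
for (cond in c("SG", "UG")) {
  m <- metrics[metrics$condition == cond, ]
  lines <- c(lines, sprintf("| %s | %s | %s | %s |", cond,
                            fmt(mean(m$cai_hip)), fmt(mean(m$cai_knee)),
                            fmt(mean(m$cai_ankle))))
}

lines <- c(lines, "", "## Postural sway", "", sprintf(
  "Mean CoP 95%% ellipse area: SG %s cm^2, UG %s cm^2.",
  fmt(summ$mean_cop_area[["SG"]] * 1e4), fmt(summ$mean_cop_area[["UG"]] * 1e4)),
  "")

writeLines(lines, file.path("results", "report.md"))
cat("report -> results/report.md\n")
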