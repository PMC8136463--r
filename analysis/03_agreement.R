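#!/usr/bin/env Rscript
# Step 3 — agreement against the consensus of experts.
#
# Builds the median-of-experts reference standard, computes signed
# deviations for the AI and for every expert treated as an individual,
# and writes the stratified agreement summaries (bias, precision SD,
# absolute-deviation quantiles, ICC) plus the comparison tests.

suppressPackageStartupMessages(library(echodim))

seed <- 2026L
study_dir <- file.path("results", "study")
out <- file.path("results", "agreement")

res <- run_validation(
  run_config(mode = "load",
             frames_csv = file.path(study_dir, "frames.csv"),
             annotations_csv = file.path(study_dir, "annotations.csv"),
             ai_id = "ai", seed = seed),
  out)

s <- res$agreement_summary
show <- function(m, d) {
  r <- s[s$method_id == m & s$dimension == d & s$phase == "pooled", ]
  cat(sprintf("%-8s %-4s: bias %+.2f mm, precision SD %.2f mm, median |dev| %.2f mm, ICC %.3f (%.3f-%.3f)\n",
              m, toupper(d), r$bias_mm, r$precision_sd_mm, r$q50_mm,
              r$icc, r$icc_ci_low, r$icc_ci_high))
}
for (d in c("lvid", "ivs", "pw")) show("ai", d)

ex <- s[s$method_id != "ai" & s$phase == "pooled" & s$available, ]
cat(sprintf("individual experts, LVID precision SD: median %.2f mm (range %.2f-%.2f)\n",
            median(ex$precision_sd_mm[ex$dimension == "lvid"]),
            min(ex$precision_sd_mm[ex$dimension == "lvid"]),
            max(ex$precision_sd_mm[ex$dimension == "lvid"])))
ph <- s[s$method_id == "ai" & s$dimension == "lvid", ]
cat(sprintf("AI LVID precision SD: %.2f mm in diastole vs %.2f mm in systole\n",
            ph$precision_sd_mm[ph$phase == "ED"],
            ph$precision_sd_mm[ph$phase == "ES"]))
cat(sprintf("report bundle in %s\n", out))
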