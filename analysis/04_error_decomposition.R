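#!/usr/bin/env Rscript
# Step 4 — anatomy of the keypoint error.
#
# Re-expresses every rater's keypoint deviations in the frame of the
# consensus measurement line (rotated so the line is vertical, rescaled
# to unit length) and summarises the transverse component (along the
# measurement, which corrupts the dimension) against the longitudinal
# one (a slide along the myocardium, which barely does).  This is the
# mechanism by which dimension accuracy exceeds keypoint accuracy.

suppressPackageStartupMessages(library(echodim))

out <- file.path("results", "agreement")
ds <- read.csv(file.path(out, "decomposition_summary.csv"))

pick <- function(m, ph) ds[ds$method_id == m & ds$dimension == "lvid" &
                             ds$phase == ph & ds$point_end == "pooled", ]
for (m in c("ai", "experts")) {
  for (ph in c("pooled", "ED", "ES")) {
    r <- pick(m, ph)
    cat(sprintf("%-8s LVID %-6s: longitudinal SD %.1f%% vs transverse %.1f%% (F=%.1f, p=%.2g, n=%d)\n",
                m, ph, r$sd_longitudinal_pct, r$sd_transverse_pct,
                r$f_long_vs_trans, r$p_long_vs_trans, r$n))
  }
}
post <- ds[ds$method_id == "ai" & ds$dimension == "lvid" &
             ds$phase == "pooled" & ds$point_end != "pooled", ]
cat(sprintf("AI posterior vs anterior point, longitudinal SD: %.1f%% vs %.1f%%\n",
            post$sd_longitudinal_pct[post$point_end == "posterior"],
            post$sd_longitudinal_pct[post$point_end == "anterior"]))
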