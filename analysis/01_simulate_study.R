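#!/usr/bin/env Rscript
# Step 1 — synthesize the validation study.
#
# Generates the phantom PLAX-like study the rest of the analysis runs on:
# 100 studies, each contributing one end-diastolic and one end-systolic
# frame (200 frames), read twice by 13 blinded simulated experts plus one
# AI rater.  Writes frames (PNG), frame metadata, ground truth and the
# annotation table under results/study/.

suppressPackageStartupMessages(library(echodim))

seed <- 2026L
out <- file.path("results", "study")

cfg <- study_config(phantom = phantom_config(n_studies = 100))
syn <- generate_validation_study(cfg, seed = seed, out_dir = out)

cat(sprintf("wrote %d frames, %d annotation rows to %s\n",
            nrow(syn$frames_meta), nrow(syn$annotations), out))
cat(sprintf("raters: %d experts x %d readings + %s\n",
            cfg$n_experts, cfg$n_readings, syn$ai_id))
stopifnot(nrow(syn$frames_meta) == 200,
          nrow(syn$annotations) == 200 * 27 * 4)
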