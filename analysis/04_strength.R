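#!/usr/bin/env Rscript
# Step 4 -- promoter strength from the plate: blank subtraction,
# fluorescence-per-OD normalization, triplicate aggregation, folds vs
# P_GPD1, strength classes, and phase/medium responsiveness.
source("analysis/00_config.R")

cfg <- analysis_config()
prof <- stage_strength(cfg, OUT_DIR)

print(prof)
resp <- prof$responsiveness
cat("Phase-responsive promoters (ratio >= 2 or <= 0.5):",
    sum(resp$flags$phase_responsive), "\n")
cat("Largest stationary/logarithmic ratio:",
    signif(max(resp$phase_ratios$phase_ratio[
      is.finite(resp$phase_ratios$phase_ratio)]), 3), "\n")
cat("Extreme in all media:",
    paste(prof$classes$promoter_id[prof$classes$extreme_in_all_media],
          collapse = ", "), "\n")
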