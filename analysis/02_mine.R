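#!/usr/bin/env Rscript
# Step 2 -- mine promoter candidates: rank the top-15 genes in each of the
# eight (medium, phase) conditions, merge and deduplicate the lists, and
# extract the 1000 bp upstream windows (strand-aware, anchored at the
# translational start codon).
source("analysis/00_config.R")

cfg <- analysis_config()
cands <- stage_mine(cfg, OUT_DIR)

cat("Candidates after deduplication:", nrow(cands), "\n")
cat("Support distribution (conditions per candidate):\n")
print(table(cands$n_conditions))
cat("Truncated upstream windows:", sum(cands$truncated), "\n")
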