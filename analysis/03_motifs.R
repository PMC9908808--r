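#!/usr/bin/env Rscript
# Step 3 -- core element and splice-risk scan of the mined promoters:
# literal CAAT and GC-box (GGGCGGG) occurrences, the pyrimidine-rich CT box
# within -90..-10 of the start codon, and cryptic G|GT / AG|G splice pairs
# across the junction with the 22 bp EGFP reporter head.
source("analysis/00_config.R")

cfg <- analysis_config()
motifs <- stage_motifs(cfg, OUT_DIR)

cat("Promoters scanned:", nrow(motifs), "\n")
cat("  with >=1 CAAT:", sum(motifs$n_caat > 0),
    "| with >=1 GC box:", sum(motifs$n_gc_box > 0), "\n")
cat("  CT box called (C+T fraction >= 0.6 in a 20 bp window):",
    sum(motifs$ct_box_found), "\n")
cat("  splice risk at the reporter junction:", sum(motifs$splice_risk), "\n")
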