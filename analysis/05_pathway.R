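#!/usr/bin/env Rscript
# Step 5 -- combinatorial pathway optimization and the consolidated report:
# score the promoter-pair designs from the strength matrix, rank measured
# C18:2 titers, compute improvements over the reference-pair strain, and
# summarise mixed-sugar utilization.
source("analysis/00_config.R")

cfg <- analysis_config()
path_res <- stage_pathway(cfg, OUT_DIR)
rep_ <- stage_report(cfg, OUT_DIR)

cat("Best design and improvement vs the P_GPD1/P_GPD1 pair:\n")
print(path_res$improvement[, c("medium", "best_strain",
                               "improvement_vs_reference_pct")])
cat("\nSugar utilization at 30 h:\n")
print(path_res$sugars[, c("sugar", "consumed_fraction")])
cat("\nConsolidated report written to", file.path(OUT_DIR, "report.tsv"), "\n")
cat(sprintf("Cascade: %d candidates -> %d assayed -> %d strong (+%d controls = %d)\n",
            rep_$n_candidates, rep_$n_assayed, rep_$n_strong,
            rep_$n_controls, rep_$n_strong_incl_controls))
cat(sprintf("Fold span (strong class): %.3g at %s to %.3g at %s\n",
            rep_$fold_min, rep_$fold_min_at, rep_$fold_max, rep_$fold_max_at))
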