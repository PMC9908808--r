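# Shared configuration for the analysis drivers: the default study
# conditions (4 media x 2 growth phases, top-15 ranking, 52-candidate
# screening cascade, 0.1-19x strength span, triplicate wells at 5% CV).
# Every driver rebuilds this object, so each step can be re-run alone.
library(promotermine)

ANALYSIS_SEED <- 1L
OUT_DIR <- "results/pipeline"

analysis_config <- function(seed = ANALYSIS_SEED) {
  pipeline_config(sim = sim_config(seed = seed))
}
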