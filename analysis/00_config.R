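# Shared settings for the analysis scripts. Each numbered script can be run
# on its own (later stages regenerate what they need deterministically) or in
# sequence from the repository root:
#   Rscript analysis/01_simulate.R; Rscript analysis/02_impact.R; ...
library(reefpressure)

SEED <- 7
WORLD_DIR <- "results/world"
RESULTS_DIR <- "results"
dir.create(RESULTS_DIR, showWarnings = FALSE)

study_config <- function() {
  # the default study conditions: 64 x 64 plane (10 km cells), 6 countries,
  # 10 BCUs, the 19-stressor registry, category trends rising for climate,
  # flat for land, falling for marine
  world_config(seed = SEED)
}
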