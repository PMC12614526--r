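## Shared settings for the analysis scripts: one simulated study, fixed
## seed, raw quarterly files under scratch/ (regenerable, large), derived
## tables under results/.
library(shockscreen)

STUDY_SEED <- 20240501
RAW_DIR <- file.path("scratch", "faers_sim")
RESULTS_DIR <- "results"
study_config <- function() signal_scenario_config(seed = STUDY_SEED)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
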