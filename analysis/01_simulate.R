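#!/usr/bin/env Rscript
## Simulate the study corpus: a FAERS-style spontaneous-report database
## with planted single-drug shock signals (relative rate 5) and two
## interaction-only drug-pair signals (relative rate 6), written out as
## "$"-delimited quarterly files.
source(file.path("analysis", "00_settings.R"))

cfg <- study_config()
print(cfg)
sim <- simulate_faers(cfg)
print(sim)
paths <- write_quarterly_files(sim, RAW_DIR)
cat("wrote", length(paths), "quarterly files under", RAW_DIR, "\n")
cat("planted truth:\n")
for (s in sim$truth) {
  cat(sprintf("  %-35s -> %-10s rate %.1f%s\n",
              paste(s$exposure, collapse = " + "), s$event_term,
              s$relative_rate, if (s$interaction_only) " (interaction only)" else ""))
}
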