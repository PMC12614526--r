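#!/usr/bin/env Rscript
## Ingest the quarterly files and run the screening pipeline:
## deduplication by (CASEID, max FDA_DT, max PRIMARYID), deletion lists,
## healthcare-professional filter, demographic cleaning and shock-term
## extraction. Writes the case-level cohort and the filter audit.
source(file.path("analysis", "00_settings.R"))

cfg <- study_config()
cohort <- cohort_from_dir(RAW_DIR, cfg$quarters)
print(cohort)
cat("filter audit:\n")
audit <- data.frame(stage = names(cohort$audit),
                    count = unlist(cohort$audit), row.names = NULL)
print(audit)
data.table::fwrite(cohort$cases, file.path(RESULTS_DIR, "cohort_cases.tsv"),
                   sep = "\t")
data.table::fwrite(audit, file.path(RESULTS_DIR, "filter_audit.tsv"),
                   sep = "\t")
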