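#!/usr/bin/env Rscript
## Descriptive characteristics of the shock reports: counts and
## percentages by gender, age group, year, reporter, region, country and
## seriousness, plus the continuous-age summary.
source(file.path("analysis", "00_settings.R"))

cfg <- study_config()
cohort <- cohort_from_dir(RAW_DIR, cfg$quarters)
shock_cases <- cohort$cases[cohort$cases$is_shock]
cat(nrow(shock_cases), "shock reports of", nrow(cohort$cases), "\n")
s <- summarize_cohort(shock_cases)
print(s[s$variable %in% c("gender", "seriousness")])
cat("age summary (years):\n")
str(attr(s, "age_stats"))
data.table::fwrite(s, file.path(RESULTS_DIR, "descriptive_summary.tsv"),
                   sep = "\t")
jsonlite::write_json(attr(s, "age_stats"),
                     file.path(RESULTS_DIR, "age_summary.json"),
                     auto_unbox = TRUE, digits = NA)
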