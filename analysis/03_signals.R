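#!/usr/bin/env Rscript
## Four-method disproportionality screen (ROR, PRR + chi-squared, BCPNN
## information component, EBGM) over every drug with >= 3 shock
## co-reports, with the combined signal tiers.
source(file.path("analysis", "00_settings.R"))

cfg <- study_config()
cohort <- cohort_from_dir(RAW_DIR, cfg$quarters)
signals <- screen_signals(cohort, min_a = 3)
cat(attr(signals, "n_tests"), "drugs tested;", nrow(signals),
    "with >= 3 shock co-reports\n")
cat("tier counts:\n")
print(table(signals$tier))
cat("top 10 by case count:\n")
print(signals[1:10, c("drug", "a", "ror", "ror_l95", "prr", "chi2",
                      "ic025", "ebgm05", "n_positive", "tier")])
data.table::fwrite(signals, file.path(RESULTS_DIR, "signals.tsv"), sep = "\t")
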