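#!/usr/bin/env Rscript
## Omega shrinkage screen of co-administered drug pairs: top 30 pairs by
## shock co-report frequency, plus the full qualifying edge list.
source(file.path("analysis", "00_settings.R"))

cfg <- study_config()
cohort <- cohort_from_dir(RAW_DIR, cfg$quarters)
pairs <- screen_pairs(cohort, omega_config(), top_n = 30)
cat(nrow(attr(pairs, "edges")), "qualifying pairs;",
    sum(pairs$flagged), "of the top", nrow(pairs), "flagged\n")
print(pairs)
data.table::fwrite(pairs, file.path(RESULTS_DIR, "pairs_top30.tsv"), sep = "\t")
data.table::fwrite(attr(pairs, "edges"),
                   file.path(RESULTS_DIR, "pair_edges.tsv"), sep = "\t")
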