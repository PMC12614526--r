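test_that("deduplication keeps the latest FDA_DT, then the highest PRIMARYID", {
  # both rules forced in one case history
  d <- demo_rows(caseid = c(100, 100, 100),
                 primaryid = c(1001, 1002, 1003),
                 fda_dt = c("20200101", "20200301", "20200301"))
  out <- deduplicate_cases(d)
  expect_equal(nrow(out), 1L)
  expect_equal(out$primaryid, "1003")

  # single-version case maps to itself
  single <- demo_rows(7, 71, "20190101")
  expect_equal(as.data.frame(deduplicate_cases(single)),
               as.data.frame(single), ignore_attr = TRUE)

  # 3 cases x 2 versions -> 3 rows
  d3 <- demo_rows(caseid = rep(1:3, each = 2), primaryid = 11:16,
                  fda_dt = rep(c("20200101", "20200202"), 3))
  expect_equal(nrow(deduplicate_cases(d3)), 3L)
})

test_that("deduplication is idempotent and order-invariant", {
  set.seed(42)
  n_case <- 60
  reps <- sample(1:4, n_case, replace = TRUE)
  d <- demo_rows(
    caseid = rep(seq_len(n_case), reps),
    primaryid = sample(1e6, sum(reps)),
    fda_dt = format(as.Date("2020-01-01") + sample(0:400, sum(reps), TRUE),
                    "%Y%m%d"))
  once <- deduplicate_cases(d)
  twice <- deduplicate_cases(once)
  expect_equal(as.data.frame(once), as.data.frame(twice), ignore_attr = TRUE)
  for (i in 1:5) {
    perm <- deduplicate_cases(d[sample(nrow(d))])
    data.table::setkeyv(perm, "caseid")
    srt <- data.table::copy(once)
    data.table::setkeyv(srt, "caseid")
    expect_equal(as.data.frame(perm), as.data.frame(srt), ignore_attr = TRUE)
  }
})

test_that("deduplication handles bad identifiers and dates defensively", {
  d <- rbind(
    demo_rows(1, 11, "20200101"),
    demo_rows(1, 12, "not-a-date"),   # unparseable date sorts lowest
    demo_rows("", 13, "20200601"),    # missing caseid -> dropped
    demo_rows(2, "", "20200601"))     # missing primaryid -> dropped
  expect_warning(out <- deduplicate_cases(d), "2 row")
  expect_equal(out$primaryid, "11")
  expect_equal(attr(out, "dropped"), 2L)

  # non-numeric PRIMARYIDs fall back to lexicographic comparison
  lex <- demo_rows(c(5, 5), c("AB-2", "AB-10"), c("20200101", "20200101"))
  expect_equal(deduplicate_cases(lex)$primaryid, "AB-2")
  # numeric ones compare by value, not as strings
  num <- demo_rows(c(6, 6), c("2", "10"), c("20200101", "20200101"))
  expect_equal(deduplicate_cases(num)$primaryid, "10")
})

test_that("deletion lists remove whole cases and ignore unknown ids", {
  cases <- demo_rows(1:10, 101:110, "20200101")
  dele <- data.table(caseid = c("3", "7"))
  out <- apply_deletions(cases, dele)
  expect_equal(nrow(out), 8L)
  expect_false(any(out$caseid %in% c("3", "7")))
  expect_equal(out$caseid, setdiff(as.character(1:10), c("3", "7")))

  expect_equal(nrow(apply_deletions(cases, NULL)), 10L)
  unk <- apply_deletions(cases, data.table(caseid = "999"))
  expect_equal(nrow(unk), 10L)
  expect_equal(attr(unk, "n_unknown_deletions"), 1L)
})

test_that("healthcare-professional filtering keeps exactly MD, PH, OT", {
  cases <- demo_rows(1:6, 11:16, "20200101",
                     occp_cod = c("MD", "CN", "PH", "LW", "OT", ""))
  out <- filter_hcp(cases)
  expect_equal(sort(out$occp_cod), c("MD", "OT", "PH"))
  expect_equal(nrow(filter_hcp(demo_rows(1:3, 1:3, "20200101", "CN"))), 0L)
  expect_equal(nrow(filter_hcp(cases[0])), 0L)
})

test_that("age normalization converts units and rejects implausible values", {
  expect_equal(normalize_age(600, "MON"), 50, ignore_attr = TRUE)
  expect_equal(normalize_age(56, "YR"), 56, ignore_attr = TRUE)
  expect_equal(normalize_age(7, "DEC"), 70, ignore_attr = TRUE)
  expect_equal(normalize_age(730.5, "DY"), 2, ignore_attr = TRUE)
  # the 5200-year artifact seen in real shock cohorts becomes missing
  expect_true(is.na(normalize_age(5200, "YR")))
  expect_equal(attr(normalize_age(5200, "YR"), "n_implausible"), 1L)
  # missing unit: value treated as years, still subject to the cap
  expect_equal(normalize_age(80, ""), 80, ignore_attr = TRUE)
  expect_true(is.na(normalize_age(500, "")))
  expect_warning(res <- normalize_age(-5, "YR"), "negative")
  expect_true(is.na(res))
  expect_true(is.na(normalize_age(NA, "YR")))
})

test_that("age groups follow the descriptive-table boundaries", {
  expect_equal(assign_age_group(c(17.9, 18, 44.99, 45, 64.9, 65, 90, NA)),
               c("<18", "18-44", "18-44", "45-64", "45-64", ">=65", ">=65",
                 "not_specified"))
})

test_that("drug-name normalization trims, folds case and applies synonyms", {
  map <- c("METFORMIN HCL" = "METFORMIN")
  expect_equal(normalize_drug_name(" metformin HCL ", map), "METFORMIN")
  expect_equal(normalize_drug_name("Amlodipine"), "AMLODIPINE")
  expect_equal(normalize_drug_name("aspirin   \t low-dose"),
               "ASPIRIN LOW-DOSE")
  expect_true(is.na(normalize_drug_name("")))
  expect_equal(normalize_drug_name("metformin hydrochloride",
                                   demo_synonym_map()), "METFORMIN")
})

test_that("shock events are flagged case-insensitively against the term set", {
  ts <- shock_term_set()
  reac <- data.table(primaryid = c("1", "2", "3", "4"),
                     pt = c("Septic shock", "Nausea",
                            "CIRCULATORY COLLAPSE", "shock"))
  ev <- extract_events(reac, ts)
  expect_equal(ev$is_shock, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(ev$preferred_term, reac$pt)
  expect_error(term_set(character(0)), "at least one")
  expect_error(term_set(c("Shock", "SHOCK")), "duplicate")
})

test_that("a missing optional table reads as empty with a warning", {
  cfg <- sim_config(n_cases = 40, seed = 4, quarters = "2023Q2")
  dir <- withr::local_tempdir()
  write_quarterly_files(simulate_faers(cfg), dir)
  file.remove(file.path(dir, "OUTC23Q2.txt"))
  expect_warning(tabs <- read_quarter(dir, "2023Q2"), "OUTC")
  expect_equal(nrow(tabs$OUTC), 0L)
  expect_equal(nrow(tabs$DEMO), sum(simulate_faers(cfg)$demo$quarter == "2023Q2"))
  # a required table cannot be absent
  file.remove(file.path(dir, "DEMO23Q2.txt"))
  expect_error(read_quarter(dir, "2023Q2"), "DEMO")
})

test_that("a malformed header is rejected naming the missing columns", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_cases = 20, seed = 6, quarters = "2023Q1")
  write_quarterly_files(simulate_faers(cfg), dir)
  path <- file.path(dir, "REAC23Q1.txt")
  lines <- readLines(path)
  lines[1] <- "primaryid$caseid$reaction_term"
  writeLines(lines, path)
  expect_error(read_quarter(dir, "2023Q1"), "pt")
})

test_that("cohort audit counts are conserved across filter stages", {
  sim <- simulate_faers(sim_config(n_cases = 3000, duplicate_rate = 0.15,
                                   deletion_rate = 0.02, hcp_fraction = 0.8,
                                   seed = 31))
  coh <- build_cohort(sim)
  au <- coh$audit
  expect_equal(au$n_demo_rows,
               au$n_rows_dropped_missing_ids +
                 au$n_duplicate_versions_removed + au$n_after_dedup)
  expect_equal(au$n_after_dedup - au$n_deleted, au$n_after_deletion)
  expect_equal(au$n_after_deletion - au$n_non_hcp_removed, au$n_hcp)
  expect_equal(au$n_hcp, nrow(coh$cases))
  expect_equal(au$n_after_dedup, 3000L)
  # every surviving report is a healthcare-professional report
  expect_true(all(coh$cases$occp_cod %in% c("MD", "PH", "OT")))
  # no deleted case survives
  expect_false(any(coh$cases$caseid %in% sim$dele$caseid))
})
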