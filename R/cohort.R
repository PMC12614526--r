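#' Build the analysis cohort from raw FAERS-style tables
#'
#' Runs the full screening pipeline: deduplicate case versions, apply
#' deletion lists, restrict to healthcare-professional reports, clean
#' demographics (age unit conversion and plausibility cap, age grouping,
#' region assignment, reporting year from FDA_DT), standardize drug names,
#' flag shock events from the REAC table, and derive seriousness from the
#' presence of outcome rows (the FAERS convention: every OUTC code denotes
#' a serious outcome).
#'
#' The cohort keeps *all* surviving reports, shock and non-shock alike —
#' disproportionality contrasts target events against all other events in
#' the same database, so the non-shock background is part of the corpus.
#'
#' @param tables named list with elements `DEMO`, `DRUG`, `REAC`, `OUTC`,
#'   `DELE` (as returned by [read_quarters()]), or a `faers_sim` object.
#' @param shock_terms a [term_set()] defining shock preferred terms.
#' @param synonym_map optional named vector for [normalize_drug_name()].
#' @param region_map named vector for [assign_region()].
#' @param roles drug role codes counted as exposure; the default counts
#'   primary suspect, secondary suspect and concomitant (PS/SS/C) alike,
#'   set `c("PS","SS")` to restrict to suspects.
#' @return object of class `shock_cohort`: list with
#'   \describe{
#'     \item{cases}{one row per retained report: `primaryid`, `caseid`,
#'       `fda_dt`, `occp_cod`, `sex`, `age_years`, `age_group`,
#'       `reporting_year`, `country`, `region`, `serious`, `is_shock`.}
#'     \item{exposures}{unique (`primaryid`, `drug`) pairs after name
#'       standardization and role filtering.}
#'     \item{events}{per-event rows with `is_shock` flags.}
#'     \item{audit}{named list of row counts at every filter stage.}
#'   }
#' @export
build_cohort <- function(tables,
                         shock_terms = shock_term_set(),
                         synonym_map = NULL,
                         region_map = default_region_map(),
                         roles = c("PS", "SS", "C")) {
  if (inherits(tables, "faers_sim")) {
    tables <- list(DEMO = tables$demo, DRUG = tables$drug,
                   REAC = tables$reac, OUTC = tables$outc,
                   DELE = tables$dele)
  }
  demo <- as.data.table(tables$DEMO)
  audit <- list(n_demo_rows = nrow(demo))

  dd <- deduplicate_cases(demo)
  audit$n_rows_dropped_missing_ids <- attr(dd, "dropped")
  audit$n_after_dedup <- nrow(dd)
  audit$n_duplicate_versions_removed <-
    audit$n_demo_rows - audit$n_rows_dropped_missing_ids - nrow(dd)

  dd <- apply_deletions(dd, tables$DELE)
  audit$n_deleted <- attr(dd, "n_deleted")
  audit$n_unknown_deletions <- attr(dd, "n_unknown_deletions")
  audit$n_after_deletion <- nrow(dd)

  dd <- filter_hcp(dd)
  audit$n_non_hcp_removed <- attr(dd, "n_removed")
  audit$n_hcp <- nrow(dd)

  keep_ids <- dd$primaryid

  events <- extract_events(tables$REAC, shock_terms)
  events <- events[events$primaryid %in% keep_ids]
  audit$n_event_rows <- nrow(events)

  drug_raw <- as.data.table(tables$DRUG)
  drug_raw <- drug_raw[drug_raw$primaryid %in% keep_ids]
  if (!is.null(drug_raw$role_cod) && length(roles)) {
    drug_raw <- drug_raw[drug_raw$role_cod %in% roles]
  }
  std <- normalize_drug_name(drug_raw$drugname, synonym_map)
  n_blank <- sum(is.na(std))
  if (n_blank) {
    warning(sprintf("dropping %d drug row(s) with empty drug name", n_blank),
            call. = FALSE)
  }
  exposures <- unique(data.table(primaryid = drug_raw$primaryid,
                                 drug = std)[!is.na(drug)])
  audit$n_drug_rows_dropped_blank <- n_blank
  audit$n_exposure_pairs <- nrow(exposures)

  shock_ids <- unique(events$primaryid[events$is_shock])
  serious_ids <- unique(as.data.table(tables$OUTC)$primaryid)

  age_raw <- if (is.null(dd$age)) NA_real_ else dd$age
  age_cod <- if (is.null(dd$age_cod)) "YR" else dd$age_cod
  age_years <- suppressWarnings(normalize_age(age_raw, age_cod))
  country <- if (is.null(dd$occr_country)) rep("", nrow(dd)) else dd$occr_country
  country[is.na(country)] <- ""
  sex <- if (is.null(dd$sex)) rep("", nrow(dd)) else dd$sex
  sex[!sex %in% c("F", "M")] <- "unspecified"

  cases <- data.table(
    primaryid = dd$primaryid,
    caseid = dd$caseid,
    fda_dt = dd$fda_dt,
    occp_cod = dd$occp_cod,
    sex = sex,
    age_years = as.numeric(age_years),
    age_group = assign_age_group(age_years),
    reporting_year = suppressWarnings(as.integer(substr(dd$fda_dt, 1, 4))),
    country = ifelse(nzchar(country), country, NA_character_),
    region = assign_region(country, region_map),
    serious = dd$primaryid %in% serious_ids,
    is_shock = dd$primaryid %in% shock_ids)
  audit$n_reports <- nrow(cases)
  audit$n_shock_reports <- sum(cases$is_shock)
  audit$n_implausible_ages <- attr(age_years, "n_implausible")

  structure(list(cases = cases, exposures = exposures, events = events,
                 audit = audit),
            class = "shock_cohort")
}

#' @export
print.shock_cohort <- function(x, ...) {
  cat("<shock_cohort> ", nrow(x$cases), " reports (",
      sum(x$cases$is_shock), " shock), ",
      length(unique(x$exposures$drug)), " drugs, ",
      nrow(x$exposures), " exposure pairs\n", sep = "")
  invisible(x)
}

#' Build a cohort straight from a directory of quarterly files
#'
#' Convenience wrapper: [read_quarters()] then [build_cohort()].
#'
#' @param dir directory with FAERS-style quarterly files.
#' @param quarters character vector of quarter labels.
#' @param ... passed to [build_cohort()].
#' @return a `shock_cohort`.
#' @export
cohort_from_dir <- function(dir, quarters, ...) {
  build_cohort(read_quarters(dir, quarters), ...)
}
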