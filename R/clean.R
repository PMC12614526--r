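AGE_UNIT_DIVISOR <- c(YR = 1, DEC = 0.1, MON = 12, WK = 52.1775,
                      DY = 365.25, HR = 8766)

#' Convert an age value with unit code to years
#'
#' FAERS carries age as a value plus a unit code. Supported codes: YR
#' (years), DEC (decades), MON (months), WK (weeks), DY (days), HR (hours).
#' A missing or unrecognised unit is treated as years. Results above 120
#' years are implausible (real shock cohorts carry artifacts such as an age
#' of 5200) and are set to missing, as are negative inputs (with a counted
#' warning).
#'
#' @param value numeric (or numeric-like character) vector of age values.
#' @param unit_code character vector of unit codes, recycled if length 1.
#' @return numeric vector of ages in years; `NA` where missing or
#'   implausible. Attribute `n_implausible` counts values zeroed by the
#'   plausibility cap.
#' @export
#' @examples
#' normalize_age(600, "MON")   # 50
#' normalize_age(5200, "YR")   # NA: implausible
normalize_age <- function(value, unit_code = "YR") {
  v <- suppressWarnings(as.numeric(value))
  if (length(unit_code) == 1L) unit_code <- rep(unit_code, length(v))
  neg <- !is.na(v) & v < 0
  if (any(neg)) {
    warning(sprintf("%d negative age value(s) set to missing", sum(neg)),
            call. = FALSE)
    v[neg] <- NA_real_
  }
  unit <- toupper(trimws(unit_code))
  div <- AGE_UNIT_DIVISOR[unit]
  div[is.na(div)] <- 1  # unknown or missing unit: assume years
  yrs <- v / unname(div)  # DEC's divisor of 0.1 multiplies by ten
  implausible <- !is.na(yrs) & yrs > 120
  yrs[implausible] <- NA_real_
  structure(yrs, n_implausible = sum(implausible))
}

AGE_GROUP_LEVELS <- c("<18", "18-44", "45-64", ">=65", "not_specified")

#' Assign the descriptive-table age group
#'
#' Boundaries follow the conventional strata: `[0,18)`, `[18,45)`,
#' `[45,65)`, `[65,Inf)`; missing ages go to `"not_specified"`.
#'
#' @param age_years numeric vector of ages in years (may contain `NA`).
#' @return character vector of group labels.
#' @export
assign_age_group <- function(age_years) {
  out <- rep("not_specified", length(age_years))
  ok <- !is.na(age_years)
  out[ok & age_years < 18] <- "<18"
  out[ok & age_years >= 18 & age_years < 45] <- "18-44"
  out[ok & age_years >= 45 & age_years < 65] <- "45-64"
  out[ok & age_years >= 65] <- ">=65"
  out
}

#' Standardize a drug name
#'
#' Trims, collapses internal whitespace and uppercases the raw name, then
#' applies an exact-match synonym lookup on the normalized form (standing in
#' for a licensed drug dictionary). Unmapped names pass through normalized.
#' Empty raw names return `NA` (callers drop such records with a counted
#' warning).
#'
#' @param raw character vector of raw drug names.
#' @param synonym_map named character vector (normalized raw -> standard),
#'   e.g. [demo_synonym_map()], or `NULL` for none.
#' @return character vector of standardized names (`NA` where empty).
#' @export
#' @examples
#' normalize_drug_name(" metformin HCL ", demo_synonym_map())  # "METFORMIN"
normalize_drug_name <- function(raw, synonym_map = NULL) {
  std <- toupper(gsub("\\s+", " ", trimws(raw)))
  std[is.na(std) | !nzchar(std)] <- NA_character_
  if (!is.null(synonym_map) && length(synonym_map)) {
    hit <- match(std, names(synonym_map))
    std[!is.na(hit)] <- unname(synonym_map[hit[!is.na(hit)]])
  }
  std
}

#' Extract event records and flag shock terms
#'
#' Every REAC row yields one event record; `is_shock` is true exactly when
#' the case-folded preferred term is in the term set. A report's shock
#' status is the OR over its events (see [build_cohort()]).
#'
#' @param reac data.frame of REAC rows with columns `primaryid`, `pt`.
#' @param termset a [term_set()], typically [shock_term_set()].
#' @return data.table with columns `primaryid`, `preferred_term`, `is_shock`.
#' @export
extract_events <- function(reac, termset = shock_term_set()) {
  if (!inherits(termset, "term_set")) stop_config("termset must be a term_set")
  r <- as.data.table(reac)
  data.table(primaryid = r$primaryid,
             preferred_term = r$pt,
             is_shock = toupper(trimws(r$pt)) %in% termset$folded)
}

#' Map countries to reporting regions
#'
#' @param country character vector of ISO-2 country codes (may be empty or
#'   `NA`).
#' @param region_map named vector country -> region, see
#'   [default_region_map()].
#' @return character vector of regions; unknown or missing countries give
#'   `"not_specified"`.
#' @export
assign_region <- function(country, region_map = default_region_map()) {
  out <- unname(region_map[country])
  out[is.na(out)] <- "not_specified"
  out
}
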