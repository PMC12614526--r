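#' Default per-report baseline probabilities for shock preferred terms
#'
#' Baselines are chosen so that roughly 2% of reports carry at least one
#' shock term, with "Shock" itself dominating — the shape seen in
#' spontaneous-report databases where the generic term far outnumbers the
#' aetiology-specific ones.
#'
#' @return named numeric vector (preferred term -> per-report probability).
#' @export
default_shock_baselines <- function() {
  c("Shock"                = 0.015,
    "Septic shock"         = 0.0015,
    "Anaphylactic shock"   = 0.0010,
    "Cardiogenic shock"    = 0.0008,
    "Hypovolemic shock"    = 0.0004,
    "Circulatory collapse" = 0.0004,
    "Distributive shock"   = 0.0002,
    "Neurogenic shock"     = 0.0002,
    "Obstructive shock"    = 0.0001,
    "Toxic shock syndrome" = 0.0001)
}

#' Default baseline probabilities for non-shock background events
#' @return named numeric vector (preferred term -> per-report probability).
#' @export
default_background_baselines <- function() {
  c("Nausea"           = 0.060,
    "Drug ineffective" = 0.050,
    "Headache"         = 0.050,
    "Fatigue"          = 0.040,
    "Diarrhoea"        = 0.040,
    "Vomiting"         = 0.035,
    "Dizziness"        = 0.035,
    "Dyspnoea"         = 0.030,
    "Rash"             = 0.030,
    "Pyrexia"          = 0.030,
    "Off label use"    = 0.030,
    "Pruritus"         = 0.020,
    "Arthralgia"       = 0.020,
    "Insomnia"         = 0.020,
    "Anaemia"          = 0.015)
}

#' Declare a planted ground-truth signal
#'
#' @param exposure a single drug name, or a character vector of two drug
#'   names for a drug-pair signal. Names must exist in the simulated drug
#'   universe.
#' @param event_term one preferred term from the configured shock or
#'   background term lists, or `"any_shock"` to apply the multiplier to
#'   every shock term (a drug-level shock signal).
#' @param relative_rate multiplier (> 0) applied to the event's baseline
#'   per-report probability among exposed reports (capped at 1).
#' @param interaction_only for a pair exposure: if `TRUE` the multiplier
#'   applies only to reports containing both drugs (a pure interaction
#'   signal); if `FALSE` it applies to reports containing either drug.
#' @return an object of class `planted_signal`.
#' @export
planted_signal <- function(exposure, event_term, relative_rate,
                           interaction_only = FALSE) {
  exposure <- toupper(trimws(as.character(exposure)))
  if (!length(exposure) %in% 1:2 || anyDuplicated(exposure)) {
    stop_config("exposure must be one drug name or two distinct drug names")
  }
  if (!is.numeric(relative_rate) || length(relative_rate) != 1L ||
      !is.finite(relative_rate) || relative_rate <= 0) {
    stop_config("relative_rate must be a single positive number")
  }
  structure(list(exposure = sort(exposure),
                 event_term = as.character(event_term)[1L],
                 relative_rate = relative_rate,
                 interaction_only = isTRUE(interaction_only)),
            class = "planted_signal")
}

check_prob <- function(x, what, open_top = FALSE) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) ||
      any(if (open_top) x >= 1 else x > 1)) {
    stop_config("%s must be in [0,%s]", what, if (open_top) "1)" else "1]")
  }
  invisible(x)
}

#' Configure the spontaneous-report simulator
#'
#' All defaults describe the study conditions exercised throughout the
#' package: a database of 50,000 cases over 100 drugs with Zipf-distributed
#' exposure, ~2% shock-report prevalence, demographic mixes and missingness
#' patterned on large FAERS shock cohorts, a modest rate of duplicate case
#' versions and quarterly deletion lists, and reporter occupations
#' dominated by healthcare professionals.
#'
#' @param n_cases number of distinct cases (CASEIDs) to simulate.
#' @param n_drugs size of the drug universe (first `n_drugs` rows of
#'   `drug_names`).
#' @param drug_popularity_exponent Zipf exponent: drug at popularity rank
#'   `i` is sampled with probability proportional to `i^-exponent`.
#' @param background_event_terms named numeric vector of per-report baseline
#'   probabilities for non-shock preferred terms.
#' @param shock_terms named numeric vector of baseline probabilities for
#'   shock preferred terms.
#' @param planted_signals list of [planted_signal()] objects (may be empty).
#' @param duplicate_rate fraction of cases emitted with 2..`max_versions`
#'   report versions.
#' @param max_versions maximum versions per duplicated case (>= 2).
#' @param deletion_rate fraction of cases listed in quarterly deletion files.
#' @param hcp_fraction fraction of reports filed by healthcare professionals
#'   (occupation codes MD, PH, OT).
#' @param missing_sex_rate,missing_age_rate,missing_country_rate field-level
#'   missingness probabilities.
#' @param female_fraction fraction of sex-specified reports that are female.
#' @param serious_fraction fraction of reports with at least one serious
#'   outcome code (FAERS convention: any OUTC row marks a serious report).
#' @param implausible_age_rate small probability that a report carries an
#'   implausible age value (5200) with unit YR, exercising age cleaning.
#' @param mean_concomitant mean number of drugs per report beyond the first
#'   (per-report drug count is `1 + Poisson(mean_concomitant)`).
#' @param quarters character vector of quarter labels, e.g. `"2023Q1"`.
#' @param drug_names character vector naming the drug universe in popularity
#'   order; defaults to the bundled universe of [default_drug_universe()].
#' @param seed integer seed; identical configurations (including the seed)
#'   reproduce byte-identical datasets.
#' @return validated object of class `sim_config`.
#' @export
sim_config <- function(n_cases = 50000L,
                       n_drugs = 100L,
                       drug_popularity_exponent = 1,
                       background_event_terms = default_background_baselines(),
                       shock_terms = default_shock_baselines(),
                       planted_signals = list(),
                       duplicate_rate = 0.05,
                       max_versions = 3L,
                       deletion_rate = 0.005,
                       hcp_fraction = 0.9,
                       missing_sex_rate = 0.105,
                       missing_age_rate = 0.19,
                       missing_country_rate = 0.30,
                       female_fraction = 0.518,
                       serious_fraction = 0.9926,
                       implausible_age_rate = 0.002,
                       mean_concomitant = 1.5,
                       quarters = c("2023Q1", "2023Q2", "2023Q3", "2023Q4"),
                       drug_names = NULL,
                       seed = 1L) {
  if (!is.numeric(n_cases) || n_cases < 1) stop_config("n_cases must be >= 1")
  if (!is.numeric(n_drugs) || n_drugs < 1) stop_config("n_drugs must be >= 1")
  if (drug_popularity_exponent <= 0) {
    stop_config("drug_popularity_exponent must be positive")
  }
  if (length(shock_terms) == 0L || is.null(names(shock_terms))) {
    stop_config("shock_terms must be a non-empty named probability vector")
  }
  if (length(background_event_terms) == 0L ||
      is.null(names(background_event_terms))) {
    stop_config("background_event_terms must be a non-empty named probability vector")
  }
  check_prob(shock_terms, "shock term baselines")
  check_prob(background_event_terms, "background term baselines")
  check_prob(duplicate_rate, "duplicate_rate", open_top = TRUE)
  check_prob(deletion_rate, "deletion_rate", open_top = TRUE)
  check_prob(hcp_fraction, "hcp_fraction")
  check_prob(missing_sex_rate, "missing_sex_rate")
  check_prob(missing_age_rate, "missing_age_rate")
  check_prob(missing_country_rate, "missing_country_rate")
  check_prob(female_fraction, "female_fraction")
  check_prob(serious_fraction, "serious_fraction")
  check_prob(implausible_age_rate, "implausible_age_rate")
  if (max_versions < 2) stop_config("max_versions must be >= 2")
  if (length(quarters) == 0L) stop_config("quarters must be non-empty")
  if (!all(grepl("^[0-9]{4}Q[1-4]$", quarters))) {
    stop_config("quarter labels must look like 2023Q1")
  }
  drug_names <- toupper(drug_names %||% default_drug_universe()$drug)
  if (length(drug_names) < n_drugs) {
    stop_config("drug_names supplies %d names but n_drugs = %d",
                length(drug_names), n_drugs)
  }
  drug_names <- drug_names[seq_len(n_drugs)]
  all_terms <- toupper(c(names(shock_terms), names(background_event_terms)))
  for (s in planted_signals) {
    if (!inherits(s, "planted_signal")) {
      stop_config("planted_signals must be a list of planted_signal objects")
    }
    if (!all(s$exposure %in% drug_names)) {
      stop_config("planted signal exposure %s not in the drug universe",
                  paste(s$exposure, collapse = "+"))
    }
    if (!toupper(s$event_term) %in% c("ANY_SHOCK", all_terms)) {
      stop_config("planted signal event term '%s' not in the configured term lists",
                  s$event_term)
    }
  }
  structure(list(
    n_cases = as.integer(n_cases), n_drugs = as.integer(n_drugs),
    drug_popularity_exponent = drug_popularity_exponent,
    background_event_terms = background_event_terms,
    shock_terms = shock_terms, planted_signals = planted_signals,
    duplicate_rate = duplicate_rate, max_versions = as.integer(max_versions),
    deletion_rate = deletion_rate, hcp_fraction = hcp_fraction,
    missing_sex_rate = missing_sex_rate, missing_age_rate = missing_age_rate,
    missing_country_rate = missing_country_rate,
    female_fraction = female_fraction, serious_fraction = serious_fraction,
    implausible_age_rate = implausible_age_rate,
    mean_concomitant = mean_concomitant,
    quarters = quarters, drug_names = drug_names, seed = as.integer(seed)),
    class = "sim_config")
}

#' Study-condition scenario configurations
#'
#' `null_scenario_config()` plants no signals (used for false-positive
#' calibration). `signal_scenario_config()` plants ten single-drug shock
#' signals at relative reporting rate 5 (applied to the whole shock scope)
#' on drugs in the mid-to-low popularity range (ranks 51-96, expected
#' shock co-report counts of roughly 20-45 at the default corpus size),
#' plus two interaction-only drug-pair signals at relative rate 6 on
#' popular pairs. Planted exposures sit in the popularity tail so that the
#' planted drugs jointly hold only a few percent of all reports — in a
#' real database any one drug holds a tiny share, and placing strong
#' signals on the most popular of only 100 drugs would contaminate the
#' comparator with the signal itself, a small-universe artifact rather
#' than a feature of spontaneous reporting.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @return a `sim_config`.
#' @export
null_scenario_config <- function(seed = 1L, ...) {
  sim_config(planted_signals = list(), seed = seed, ...)
}

#' @rdname null_scenario_config
#' @export
signal_scenario_config <- function(seed = 1L, ...) {
  drugs <- default_drug_universe()$drug
  single_ranks <- c(51L, 56L, 61L, 66L, 71L, 76L, 81L, 86L, 91L, 96L)
  singles <- lapply(drugs[single_ranks], planted_signal,
                    event_term = "any_shock", relative_rate = 5)
  pairs <- list(
    planted_signal(drugs[c(2L, 5L)], "any_shock", 6, interaction_only = TRUE),
    planted_signal(drugs[c(4L, 6L)], "any_shock", 6, interaction_only = TRUE))
  sim_config(planted_signals = c(singles, pairs), seed = seed, ...)
}

#' Read a simulator configuration from a YAML file
#'
#' Accepts a key/value file mirroring the arguments of [sim_config()];
#' `planted_signals` entries are maps with keys `exposure`, `event_term`,
#' `relative_rate` and optional `interaction_only`.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop_config("reading YAML configurations requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$planted_signals)) {
    raw$planted_signals <- lapply(raw$planted_signals, function(s) {
      planted_signal(unlist(s$exposure), s$event_term, s$relative_rate,
                     isTRUE(s$interaction_only))
    })
  }
  for (f in c("background_event_terms", "shock_terms")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(sim_config, raw)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_cases, " cases, ", x$n_drugs, " drugs (Zipf ",
      x$drug_popularity_exponent, "), ", length(x$planted_signals),
      " planted signal(s), quarters ", paste(x$quarters, collapse = ","),
      ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}
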