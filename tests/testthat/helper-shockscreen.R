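library(data.table)

# Minimal in-memory cohort from per-report drug sets and shock flags,
# for exhaustive-enumeration tests of the contingency builders.
cohort_from_reports <- function(drugs, shock) {
  stopifnot(length(drugs) == length(shock))
  n <- length(drugs)
  pid <- sprintf("r%03d", seq_len(n))
  cases <- data.table(
    primaryid = pid, caseid = pid, fda_dt = "20230101", occp_cod = "MD",
    sex = "F", age_years = 50, age_group = "45-64", reporting_year = 2023L,
    country = "US", region = "North America", serious = TRUE,
    is_shock = shock)
  expo <- rbindlist(lapply(seq_len(n), function(i) {
    if (length(drugs[[i]]) == 0L) return(NULL)
    data.table(primaryid = pid[i], drug = toupper(drugs[[i]]))
  }))
  events <- data.table(primaryid = pid,
                       preferred_term = ifelse(shock, "Shock", "Nausea"),
                       is_shock = shock)
  structure(list(cases = cases, exposures = expo, events = events,
                 audit = list()),
            class = "shock_cohort")
}

# Raw DEMO-style rows for deduplication fixtures.
demo_rows <- function(caseid, primaryid, fda_dt, occp_cod = "MD") {
  data.table(caseid = as.character(caseid),
             primaryid = as.character(primaryid),
             fda_dt = as.character(fda_dt),
             occp_cod = occp_cod)
}

## Independent straight-line oracles: direct transcriptions of the printed
## formulas, deliberately scalar and separate from the package's vectorized
## implementations.
oracle_ror <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  est <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(est = est, l95 = exp(log(est) - 1.96 * se), u95 = exp(log(est) + 1.96 * se))
}
oracle_prr <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  est <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  n <- a + b + c + d
  chi2 <- (a * d - b * c)^2 * n / ((a + b) * (a + c) * (c + d) * (b + d))
  c(est = est, l95 = exp(log(est) - 1.96 * se),
    u95 = exp(log(est) + 1.96 * se), chi2 = chi2)
}
oracle_ic <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  nexp <- (a + b) * (a + c) / n
  ic <- log2((a + 0.5) / (nexp + 0.5))
  c(ic = ic,
    ic025 = ic - 3.3 * (a + 0.5)^(-0.5) - 2 * (a + 0.5)^(-1.5),
    ic975 = ic + 2.4 * (a + 0.5)^(-0.5) - 0.5 * (a + 0.5)^(-1.5))
}
oracle_ebgm <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  est <- a * n / ((a + c) * (a + b))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  c(est = est, ebgm05 = exp(log(est) - 1.645 * se))
}
oracle_omega <- function(a, b, c, d, s = 0.5, sf = 1, z = 1.96) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  est <- ((a + s) * (d + s)) / ((b + s) * (c + s)) * sf
  se <- sqrt(1 / (a + s) + 1 / (b + s) + 1 / (c + s) + 1 / (d + s))
  c(est = est, l95 = exp(log(est) - z * se), u95 = exp(log(est) + z * se))
}

# One shared mid-size simulated run per test file, built on first use.
.sim_cache <- new.env(parent = emptyenv())
shared_signal_run <- function() {
  if (is.null(.sim_cache$run)) {
    sim <- simulate_faers(signal_scenario_config(seed = 20240501))
    cohort <- build_cohort(sim)
    .sim_cache$run <- list(sim = sim, cohort = cohort,
                           signals = screen_signals(cohort))
  }
  .sim_cache$run
}
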