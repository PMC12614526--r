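#' Simulate a FAERS-style spontaneous report database
#'
#' Generates the five quarterly table kinds the downstream pipeline consumes
#' (DEMO, DRUG, REAC, OUTC, DELE) with known ground truth. Structural
#' features of real FAERS data are reproduced: duplicate case versions
#' sharing a CASEID but differing in FDA_DT and/or PRIMARYID (later versions
#' get a strictly larger FDA_DT with probability 0.8 and an equal FDA_DT
#' with a larger PRIMARYID otherwise, so both deduplication tie rules are
#' exercised), quarterly deletion lists, reporter occupation codes,
#' demographic missingness, age values carried with a unit code (YR, MON,
#' DY) including occasional implausible entries (5200 YR), Zipf-distributed
#' drug exposure, background event rates, and planted drug-event and
#' drug-pair-event signals whose occurrence probability among exposed
#' reports equals baseline times the planted relative rate (capped at 1).
#'
#' @param config a [sim_config()].
#' @return an object of class `faers_sim`: a list with data.tables `demo`,
#'   `drug`, `reac`, `outc`, `dele` (all character columns, plus a `quarter`
#'   assignment column used by [write_quarterly_files()]), the planted
#'   `truth`, and the echoed `config`.
#' @export
#' @examples
#' sim <- simulate_faers(sim_config(n_cases = 500, seed = 42))
#' nrow(sim$demo) >= 500
simulate_faers <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop_config("config must be built with sim_config()")
  }
  set.seed(config$seed)
  n <- config$n_cases
  nd <- config$n_drugs
  drugs <- config$drug_names

  ## --- drug exposure: 1 + Poisson concomitants, Zipf popularity, sampled
  ##     without replacement within a report
  k <- 1L + rpois(n, config$mean_concomitant)
  k <- pmin(k, nd, 10L)
  pz <- seq_len(nd)^(-config$drug_popularity_exponent)
  pz <- pz / sum(pz)
  lst <- vector("list", n)
  ones <- which(k == 1L)
  if (length(ones)) {
    lst[ones] <- as.list(sample.int(nd, length(ones), replace = TRUE, prob = pz))
  }
  for (i in which(k > 1L)) lst[[i]] <- sample.int(nd, k[i], prob = pz)
  expo <- data.table(case = rep(seq_len(n), k), drug_idx = unlist(lst))
  expo[, drug_seq := seq_len(.N), by = case]

  ## --- events: per-term Bernoulli draws, planted signals boost exposed reports
  terms <- c(config$shock_terms, config$background_event_terms)
  mult <- rep(list(NULL), length(terms))
  names(mult) <- toupper(names(terms))
  exposed_cases <- function(sig) {
    idx <- match(sig$exposure, drugs)
    if (length(idx) == 1L) return(unique(expo$case[expo$drug_idx == idx]))
    in1 <- unique(expo$case[expo$drug_idx == idx[1L]])
    in2 <- unique(expo$case[expo$drug_idx == idx[2L]])
    if (sig$interaction_only) intersect(in1, in2) else union(in1, in2)
  }
  boost <- lapply(seq_along(terms), function(j) rep(1, n))
  names(boost) <- toupper(names(terms))
  shock_keys <- toupper(names(config$shock_terms))
  for (sig in config$planted_signals) {
    keys <- if (toupper(sig$event_term) == "ANY_SHOCK") shock_keys
            else toupper(sig$event_term)
    ec <- exposed_cases(sig)
    for (key in keys) {
      boost[[key]][ec] <- pmax(boost[[key]][ec], sig$relative_rate)
    }
  }
  ev_case <- integer(0)
  ev_term <- character(0)
  for (j in seq_along(terms)) {
    p <- pmin(1, terms[[j]] * boost[[j]])
    hit <- which(runif(n) < p)
    ev_case <- c(ev_case, hit)
    ev_term <- c(ev_term, rep(names(terms)[j], length(hit)))
  }
  # every spontaneous report names at least one reaction; reports with no
  # sampled event get a neutral filler term outside the configured lists
  silent <- setdiff(seq_len(n), unique(ev_case))
  ev_case <- c(ev_case, silent)
  ev_term <- c(ev_term, rep("Product use issue", length(silent)))
  reac0 <- data.table(case = ev_case, pt = ev_term)
  setorderv(reac0, c("case", "pt"))

  ## --- case-level demographics
  sex <- ifelse(runif(n) < config$missing_sex_rate, "",
                ifelse(runif(n) < config$female_fraction, "F", "M"))
  age_miss <- runif(n) < config$missing_age_rate
  age_years <- pmin(pmax(rnorm(n, 53, 24.25), 0), 100)
  age_cod <- sample(c("YR", "MON", "DY"), n, replace = TRUE,
                    prob = c(0.97, 0.02, 0.01))
  age_val <- round(age_years * c(YR = 1, MON = 12, DY = 365.25)[age_cod])
  implausible <- runif(n) < config$implausible_age_rate
  age_val[implausible] <- 5200
  age_cod[implausible] <- "YR"
  age_str <- ifelse(age_miss, "", as.character(age_val))
  age_cod_str <- ifelse(age_miss, "", age_cod)
  is_hcp <- runif(n) < config$hcp_fraction
  occp <- character(n)
  occp[is_hcp] <- sample(c("MD", "PH", "OT"), sum(is_hcp), replace = TRUE,
                         prob = c(0.482, 0.260, 0.258))
  occp[!is_hcp] <- sample(c("CN", "LW", ""), sum(!is_hcp), replace = TRUE,
                          prob = c(0.8, 0.1, 0.1))
  cw <- c(US = 0.373, FR = 0.117, JP = 0.068, GB = 0.059, CA = 0.047,
          DE = 0.060, IT = 0.040, ES = 0.030, NL = 0.020, SE = 0.015,
          CN = 0.025, IN = 0.020, KR = 0.015, BR = 0.040, AR = 0.008,
          AU = 0.025, NZ = 0.005, ZA = 0.008, EG = 0.004, MX = 0.021)
  country <- ifelse(runif(n) < config$missing_country_rate, "",
                    sample(names(cw), n, replace = TRUE, prob = cw / sum(cw)))
  serious <- runif(n) < config$serious_fraction
  quarter <- sample(config$quarters, n, replace = TRUE)

  ## --- versions and dates
  dup <- runif(n) < config$duplicate_rate
  nver <- rep(1L, n)
  if (any(dup)) {
    nver[dup] <- sample(2:config$max_versions, sum(dup), replace = TRUE)
  }
  q_start <- quarter_start(quarter)
  base_off <- sample.int(10L, n, replace = TRUE) - 1L
  ncase_ver <- sum(nver)
  ver_case <- rep(seq_len(n), nver)
  ver_no <- sequence(nver)
  # later versions: +1..20 days with probability 0.8, same day otherwise;
  # offsets are clamped to the quarter so extreme max_versions settings
  # stay within their files
  step <- ifelse(runif(ncase_ver) < 0.8,
                 sample.int(20L, ncase_ver, replace = TRUE), 0L)
  step[ver_no == 1L] <- 0L
  off <- base_off[ver_case] +
    as.integer(stats::ave(step, ver_case, FUN = cumsum))
  off <- pmin(off, 88L)
  fda_dt <- format(q_start[ver_case] + off, "%Y%m%d")

  caseid <- as.character(100000000L + seq_len(n))
  primaryid <- paste0(caseid[ver_case], ver_no)

  demo <- data.table(
    primaryid = primaryid,
    caseid = caseid[ver_case],
    caseversion = as.character(ver_no),
    fda_dt = fda_dt,
    age = age_str[ver_case],
    age_cod = age_cod_str[ver_case],
    sex = sex[ver_case],
    occp_cod = occp[ver_case],
    occr_country = country[ver_case],
    quarter = quarter[ver_case])

  ver <- data.table(case = ver_case, primaryid = primaryid,
                    caseid = caseid[ver_case], quarter = quarter[ver_case])
  drug_tbl <- merge(ver, expo, by = "case", allow.cartesian = TRUE, sort = FALSE)
  setorderv(drug_tbl, c("case", "primaryid", "drug_seq"))
  drug <- drug_tbl[, data.table(
    primaryid = primaryid, caseid = caseid,
    drug_seq = as.character(drug_seq),
    role_cod = ifelse(drug_seq == 1L, "PS", ifelse(drug_seq == 2L, "SS", "C")),
    drugname = drugs[drug_idx], quarter = quarter)]

  reac_tbl <- merge(ver, reac0, by = "case", allow.cartesian = TRUE, sort = FALSE)
  setorderv(reac_tbl, c("case", "primaryid", "pt"))
  reac <- reac_tbl[, .(primaryid, caseid, pt, quarter)]

  outc_case <- which(serious)
  n_outc <- 1L + (runif(length(outc_case)) < 0.3)
  ow <- c(HO = 0.48, LT = 0.25, OT = 0.14, DE = 0.07, DS = 0.04,
          CA = 0.01, RI = 0.01)
  outc0 <- data.table(
    case = rep(outc_case, n_outc),
    outc_cod = sample(names(ow), sum(n_outc), replace = TRUE, prob = ow / sum(ow)))
  outc0 <- unique(outc0)
  outc_tbl <- merge(ver, outc0, by = "case", allow.cartesian = TRUE, sort = FALSE)
  setorderv(outc_tbl, c("case", "primaryid", "outc_cod"))
  outc <- outc_tbl[, .(primaryid, caseid, outc_cod, quarter)]

  del <- which(runif(n) < config$deletion_rate)
  dele <- data.table(caseid = caseid[del], quarter = quarter[del])
  setorderv(dele, "caseid")

  structure(list(demo = demo, drug = drug, reac = reac, outc = outc,
                 dele = dele, truth = config$planted_signals,
                 config = config),
            class = "faers_sim")
}

# first calendar day of each quarter label ("2023Q1" -> 2023-01-01)
quarter_start <- function(quarter) {
  yr <- substr(quarter, 1, 4)
  qn <- as.integer(substr(quarter, 6, 6))
  as.Date(paste0(yr, "-", c("01", "04", "07", "10")[qn], "-01"))
}

#' @export
print.faers_sim <- function(x, ...) {
  cat("<faers_sim> ", length(unique(x$demo$caseid)), " cases / ",
      nrow(x$demo), " report versions, ", nrow(x$drug), " drug rows, ",
      nrow(x$reac), " reaction rows, ", nrow(x$dele), " deletions, ",
      length(x$truth), " planted signal(s)\n", sep = "")
  invisible(x)
}

#' Write a simulated dataset as FAERS-style quarterly ASCII files
#'
#' Emits "$"-delimited files `DEMOyyQq.txt`, `DRUGyyQq.txt`, `REACyyQq.txt`,
#' `OUTCyyQq.txt` and `DELEyyQq.txt` (header row always present, even for
#' empty tables) for every configured quarter, the dialect read back by
#' [read_quarter()].
#'
#' @param sim a `faers_sim` from [simulate_faers()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the character vector of file paths written.
#' @export
write_quarterly_files <- function(sim, out_dir) {
  if (!inherits(sim, "faers_sim")) stop_config("sim must be a faers_sim")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (q in sim$config$quarters) {
    stem <- paste0(substr(q, 3, 4), "Q", substr(q, 6, 6))
    for (tbl in c("demo", "drug", "reac", "outc", "dele")) {
      dt <- sim[[tbl]]
      out <- dt[dt$quarter == q, setdiff(names(dt), "quarter"), with = FALSE]
      path <- file.path(out_dir, paste0(toupper(tbl), stem, ".txt"))
      data.table::fwrite(out, path, sep = "$", quote = FALSE, eol = "\n")
      paths <- c(paths, path)
    }
  }
  invisible(paths)
}
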