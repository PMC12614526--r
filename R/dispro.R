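#' Construct 2x2 contingency counts with derived margins
#'
#' Cells follow the standard disproportionality layout: `a` = target drug
#' with target event, `b` = target drug with other events, `c` = other
#' drugs with target event, `d` = other drugs with other events. Derived
#' quantities: `ntotal = a+b+c+d`, `ndrug = a+b`, `neffect = a+c`,
#' `nobserved = a` and `nexpected = ndrug*neffect/ntotal` (the expectation
#' under independence).
#'
#' @param a,b,c,d nonnegative integer vectors (recycled to common length).
#' @return data.table of class `contingency2x2` with the cells and derived
#'   columns.
#' @export
contingency <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) {
    stop_config("contingency cells must be nonnegative")
  }
  t <- data.table(a = as.numeric(a), b = as.numeric(b),
                  c = as.numeric(c), d = as.numeric(d))
  t[, `:=`(ntotal = a + b + c + d, ndrug = a + b, neffect = a + c)]
  if (any(t$ntotal < 1)) stop_config("contingency table must contain at least one report")
  t[, `:=`(nobserved = a, nexpected = ndrug * neffect / ntotal)]
  data.table::setattr(t, "class", c("contingency2x2", class(t)))
  t[]
}

# internal: indicator of the target event per report
scope_flags <- function(cohort, event_scope = "any_shock") {
  cases <- cohort$cases
  if (identical(event_scope, "any_shock")) return(cases$is_shock)
  ids <- unique(cohort$events$primaryid[
    toupper(trimws(cohort$events$preferred_term)) == toupper(trimws(event_scope))])
  cases$primaryid %in% ids
}

#' Build the drug-event 2x2 table over a cohort
#'
#' The unit of counting is the deduplicated report: a report contributes
#' once to exactly one cell, multiple mentions of the same drug collapse,
#' and for `event_scope = "any_shock"` multiple shock terms in one report
#' count once. Consequently `a+b+c+d` equals the number of reports in the
#' cohort.
#'
#' @param cohort a `shock_cohort`.
#' @param drug standardized drug name.
#' @param event_scope `"any_shock"` or one preferred term.
#' @return one-row [contingency()]; if the drug never occurs the table has
#'   `a = b = 0` and the attribute `absent = TRUE` (such tables are
#'   excluded by the screen).
#' @export
build_contingency <- function(cohort, drug, event_scope = "any_shock") {
  if (nrow(cohort$cases) == 0L) stop_config("cohort is empty")
  drug <- normalize_drug_name(drug)
  shock <- scope_flags(cohort, event_scope)
  exposed_ids <- unique(cohort$exposures$primaryid[cohort$exposures$drug == drug])
  exposed <- cohort$cases$primaryid %in% exposed_ids
  a <- sum(exposed & shock); b <- sum(exposed & !shock)
  c <- sum(!exposed & shock); d <- sum(!exposed & !shock)
  t <- contingency(a, b, c, d)
  data.table::setattr(t, "absent", a + b == 0)
  t
}

z_norm <- function(level) stats::qnorm(1 - (1 - level) / 2)

#' Reporting odds ratio with Wald interval
#'
#' `ROR = ad/bc`; `SE(ln ROR) = sqrt(1/a + 1/b + 1/c + 1/d)`; the 95%
#' interval is `exp(ln ROR +- 1.96 SE)`. Any zero cell makes the estimate
#' undefined: the result carries `NA` with the reason in `ror_note`, and
#' the signal flag downstream is forced false.
#'
#' @param t a [contingency()] (or data.frame with columns a,b,c,d); rows
#'   are processed vectorized.
#' @return data.table with `ror`, `ror_l95`, `ror_u95`, `ror_note`.
#' @export
ror_stats <- function(t) {
  with(t, {
    ok <- a > 0 & b > 0 & c > 0 & d > 0
    est <- ifelse(ok, a * d / (b * c), NA_real_)
    se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
    data.table(ror = est,
               ror_l95 = exp(log(est) - 1.96 * se),
               ror_u95 = exp(log(est) + 1.96 * se),
               ror_note = ifelse(ok, NA_character_, "zero cell"))
  })
}

#' Proportional reporting ratio with Wald interval and chi-squared
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`;
#' `SE(ln PRR) = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`; the chi-squared
#' statistic is the uncorrected `(ad-bc)^2 (a+b+c+d) /
#' ((a+b)(a+c)(c+d)(b+d))` (no Yates continuity correction).
#'
#' @inheritParams ror_stats
#' @return data.table with `prr`, `prr_l95`, `prr_u95`, `chi2`, `prr_note`.
#' @export
prr_stats <- function(t) {
  with(t, {
    ok <- a > 0 & (a + b) > 0 & c > 0 & (c + d) > 0
    est <- ifelse(ok, (a / (a + b)) / (c / (c + d)), NA_real_)
    se <- ifelse(ok, sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d)), NA_real_)
    n <- a + b + c + d
    chi_ok <- (a + b) > 0 & (a + c) > 0 & (c + d) > 0 & (b + d) > 0
    chi2 <- ifelse(chi_ok,
                   (a * d - b * c)^2 * n / ((a + b) * (a + c) * (c + d) * (b + d)),
                   NA_real_)
    data.table(prr = est,
               prr_l95 = exp(log(est) - 1.96 * se),
               prr_u95 = exp(log(est) + 1.96 * se),
               chi2 = chi2,
               prr_note = ifelse(ok, NA_character_, "zero cell or margin"))
  })
}

#' Hyperparameters of the Bayesian confidence propagation neural network
#'
#' Defaults are the standard flat priors: `alpha1 = beta1 = 1`,
#' `alpha = beta = 2`, `gamma11 = 1`.
#'
#' @param alpha1,beta1,alpha,beta,gamma11 prior parameters.
#' @return list of class `bcpnn_params`.
#' @export
bcpnn_params <- function(alpha1 = 1, beta1 = 1, alpha = 2, beta = 2,
                         gamma11 = 1) {
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha = alpha, beta = beta,
                 gamma11 = gamma11), class = "bcpnn_params")
}

#' Information component (BCPNN) in closed form
#'
#' Two variants are computed. The primary, credibility-interval form used
#' for signalling is
#' `IC = log2((Nobserved + 0.5) / (Nexpected + 0.5))` with
#' `IC025 = IC - 3.3 (Nobserved+0.5)^{-1/2} - 2 (Nobserved+0.5)^{-3/2}` and
#' `IC975 = IC + 2.4 (Nobserved+0.5)^{-1/2} - 0.5 (Nobserved+0.5)^{-3/2}`,
#' where `Nexpected = Ndrug * Neffect / Ntotal`. The expectation/variance
#' variant reports `E(IC)`, `V(IC)` and `IC - 2SD` under the BCPNN priors
#' in `params`, for comparison with the credibility bound.
#'
#' Both forms are defined for every nonnegative table (the 0.5 smoothing
#' keeps logs finite), so no undefined marker is needed.
#'
#' @inheritParams ror_stats
#' @param params a [bcpnn_params()].
#' @return data.table with `ic`, `ic025`, `ic975`, `ic_e`, `ic_v`,
#'   `ic_minus_2sd`.
#' @export
bcpnn_stats <- function(t, params = bcpnn_params()) {
  p <- params
  with(t, {
    n <- a + b + c + d
    nexp <- (a + b) * (a + c) / n
    s <- a + 0.5
    ic <- log2(s / (nexp + 0.5))
    ic025 <- ic - 3.3 * s^(-0.5) - 2 * s^(-1.5)
    ic975 <- ic + 2.4 * s^(-0.5) - 0.5 * s^(-1.5)
    gamma <- p$gamma11 * (n + p$alpha) * (n + p$beta) /
      ((a + b + p$alpha1) * (a + c + p$beta1))
    ic_e <- log2((a + p$gamma11) * (n + p$alpha) * (n + p$beta) /
                   ((n + gamma) * (a + b + p$alpha1) * (a + c + p$beta1)))
    ic_v <- (1 / log(2)^2) * (
      (n - a + gamma - p$gamma11) / ((a + p$gamma11) * (1 + n + gamma)) +
      (n - (a + b) + p$alpha - p$alpha1) / ((a + b + p$alpha1) * (1 + n + p$alpha)) +
      (n - (a + c) + p$beta - p$beta1) / ((a + c + p$beta1) * (1 + n + p$beta)))
    data.table(ic = ic, ic025 = ic025, ic975 = ic975,
               ic_e = ic_e, ic_v = ic_v,
               ic_minus_2sd = ic_e - 2 * sqrt(ic_v))
  })
}

#' Empirical Bayes geometric mean (relative reporting ratio form)
#'
#' `EBGM = a * Ntotal / ((a+c)(a+b))`, i.e. the observed-to-expected
#' relative reporting ratio, with `SE(ln EBGM) = sqrt(1/a+1/b+1/c+1/d)`.
#' `EBGM05`, the 90% lower bound `exp(ln EBGM - 1.645 SE)`, drives the
#' signal flag; the symmetric 95% interval is also reported. This is the
#' closed form without a fitted gamma-mixture prior — a full
#' multi-item gamma Poisson shrinker is out of scope here.
#'
#' @inheritParams ror_stats
#' @return data.table with `ebgm`, `ebgm05`, `ebgm_l95`, `ebgm_u95`,
#'   `ebgm_note`.
#' @export
ebgm_stats <- function(t) {
  with(t, {
    ok <- a > 0 & b > 0 & c > 0 & d > 0
    n <- a + b + c + d
    est <- ifelse(ok, a * n / ((a + c) * (a + b)), NA_real_)
    se <- ifelse(ok, sqrt(1 / a + 1 / b + 1 / c + 1 / d), NA_real_)
    data.table(ebgm = est,
               ebgm05 = exp(log(est) - 1.645 * se),
               ebgm_l95 = exp(log(est) - 1.96 * se),
               ebgm_u95 = exp(log(est) + 1.96 * se),
               ebgm_note = ifelse(ok, NA_character_, "zero cell"))
  })
}

TIER_LEVELS <- c("none", "weak", "three_method", "four_method")

#' Apply the per-method signal criteria and combined tiers
#'
#' Criteria: `ror+` requires ROR > 1 and its 95% lower bound > 1;
#' `prr+` requires PRR > 2 and chi-squared >= 4; `bcpnn+` requires the
#' credibility-interval IC025 > 0; `ebgm+` requires EBGM05 > 2. Every flag
#' additionally requires at least `min_a` co-reports (default 3); an
#' undefined statistic yields a false flag. Tiers: `none` (0 methods),
#' `weak` (1-2), `three_method` (3), `four_method` (4).
#'
#' @param stats data.table holding the columns produced by [ror_stats()],
#'   [prr_stats()], [bcpnn_stats()], [ebgm_stats()] plus the cell `a`.
#' @param min_a minimum number of target co-reports.
#' @return the input with added logical columns `ror_pos`, `prr_pos`,
#'   `bcpnn_pos`, `ebgm_pos`, integer `n_positive` and character `tier`.
#' @export
classify_signals <- function(stats, min_a = 3) {
  s <- as.data.table(stats)
  enough <- s$a >= min_a
  flag <- function(x) enough & !is.na(x) & x
  s[, `:=`(
    ror_pos = flag(s$ror > 1 & s$ror_l95 > 1),
    prr_pos = flag(s$prr > 2 & s$chi2 >= 4),
    bcpnn_pos = flag(s$ic025 > 0),
    ebgm_pos = flag(s$ebgm05 > 2))]
  s[, n_positive := as.integer(ror_pos) + as.integer(prr_pos) +
      as.integer(bcpnn_pos) + as.integer(ebgm_pos)]
  s[, tier := c("none", "weak", "weak", "three_method",
                "four_method")[n_positive + 1L]]
  s[]
}

#' Screen every drug in a cohort for shock association
#'
#' Builds the report-level 2x2 table for each drug with at least `min_a`
#' target co-reports, computes all four disproportionality statistics,
#' applies the signal criteria, and returns one row per drug sorted by
#' descending case count `a` with alphabetical tie-break.
#'
#' @param cohort a `shock_cohort`.
#' @param min_a minimum target co-reports for inclusion (default 3).
#' @param event_scope `"any_shock"` (default) or a single preferred term.
#' @param params a [bcpnn_params()].
#' @return data.table with the drug, cells, every statistic, flags,
#'   `n_positive` and `tier`. Attribute `n_tests` records the number of
#'   drug-event tests performed (no multiplicity correction is applied).
#' @export
screen_signals <- function(cohort, min_a = 3, event_scope = "any_shock",
                           params = bcpnn_params()) {
  cases <- cohort$cases
  if (nrow(cases) == 0L) {
    return(data.table(drug = character(0)))
  }
  shock <- scope_flags(cohort, event_scope)
  flags <- data.table(primaryid = cases$primaryid, is_target = shock)
  expo <- unique(cohort$exposures[, .(primaryid, drug)])
  m <- merge(expo, flags, by = "primaryid")
  per_drug <- m[, .(ndrug = .N, a = sum(is_target)), by = drug]
  n_total <- nrow(cases)
  n_effect <- sum(shock)
  # double precision: chi-squared products overflow 32-bit integers
  per_drug[, `:=`(a = as.numeric(a),
                  b = as.numeric(ndrug - a),
                  c = as.numeric(n_effect - a),
                  d = as.numeric(n_total - ndrug - (n_effect - a)))]
  n_tests <- nrow(per_drug)
  per_drug <- per_drug[a >= min_a]
  if (nrow(per_drug) == 0L) {
    out <- data.table(drug = character(0))
    data.table::setattr(out, "n_tests", n_tests)
    return(out)
  }
  t <- per_drug[, .(a, b, c, d)]
  res <- cbind(per_drug[, .(drug, a, b, c, d)],
               ror_stats(t), prr_stats(t), bcpnn_stats(t, params),
               ebgm_stats(t))
  res <- classify_signals(res, min_a = min_a)
  res$event_scope <- event_scope
  setorderv(res, c("a", "drug"), order = c(-1L, 1L))
  data.table::setattr(res, "n_tests", n_tests)
  res[]
}
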