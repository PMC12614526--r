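#' Configuration for the omega shrinkage screen
#'
#' The +0.5 cell smoothing is the operative shrinkage: it pulls extreme
#' odds ratios from sparse tables toward the null. `shrinkage_factor` is a
#' multiplicative hook on the final estimate (default 1) kept configurable
#' for prior-based calibrations.
#'
#' @param smoothing additive cell smoothing (> 0, default 0.5).
#' @param shrinkage_factor multiplier on the smoothed odds ratio (> 0).
#' @param z_level z quantile for the interval (default 1.96, a 95% Wald
#'   interval on the log scale).
#' @param min_a minimum target co-reports for a pair to be flagged.
#' @return list of class `omega_config`.
#' @export
omega_config <- function(smoothing = 0.5, shrinkage_factor = 1,
                         z_level = 1.96, min_a = 3) {
  if (smoothing <= 0) stop_config("smoothing must be positive")
  if (shrinkage_factor <= 0) stop_config("shrinkage_factor must be positive")
  structure(list(smoothing = smoothing, shrinkage_factor = shrinkage_factor,
                 z_level = z_level, min_a = as.integer(min_a)),
            class = "omega_config")
}

#' Omega shrinkage-adjusted odds ratio
#'
#' `Omega = ((a+s)(d+s)) / ((b+s)(c+s)) * shrinkage_factor` with smoothing
#' `s`, interval on the log scale with
#' `SE = sqrt(1/(a+s) + 1/(b+s) + 1/(c+s) + 1/(d+s))`. Values above 1
#' indicate potential safety signals. The smoothing makes the estimate
#' finite for any nonnegative table; the flag additionally requires
#' `a >= min_a` and a lower bound above 1.
#'
#' @param t a [contingency()] or data.frame with columns a,b,c,d
#'   (vectorized over rows).
#' @param cfg an [omega_config()].
#' @return data.table with `omega`, `omega_l95`, `omega_u95`, `flagged`.
#' @export
omega_stats <- function(t, cfg = omega_config()) {
  s <- cfg$smoothing
  z <- cfg$z_level
  with(t, {
    est <- ((a + s) * (d + s)) / ((b + s) * (c + s)) * cfg$shrinkage_factor
    se <- sqrt(1 / (a + s) + 1 / (b + s) + 1 / (c + s) + 1 / (d + s))
    lo <- exp(log(est) - z * se)
    hi <- exp(log(est) + z * se)
    data.table(omega = est, omega_l95 = lo, omega_u95 = hi,
               flagged = a >= cfg$min_a & lo > 1)
  })
}

#' Build the 2x2 table for a drug pair
#'
#' Exposure is the co-occurrence of both drugs in one report: `a` = pair
#' and target event, `b` = pair without the event, `c` = event without the
#' pair, `d` = neither, so `a+b+c+d` equals the cohort size. The pair is
#' unordered.
#'
#' @param cohort a `shock_cohort`.
#' @param drugA,drugB distinct standardized drug names.
#' @param event_scope `"any_shock"` or one preferred term.
#' @return one-row [contingency()]; a never-co-occurring pair gives
#'   `a = b = 0` with attribute `absent = TRUE`.
#' @export
build_pair_contingency <- function(cohort, drugA, drugB,
                                   event_scope = "any_shock") {
  if (nrow(cohort$cases) == 0L) stop_config("cohort is empty")
  drugA <- normalize_drug_name(drugA)
  drugB <- normalize_drug_name(drugB)
  if (identical(drugA, drugB)) stop_config("drugA and drugB must differ")
  shock <- scope_flags(cohort, event_scope)
  inA <- cohort$cases$primaryid %in%
    cohort$exposures$primaryid[cohort$exposures$drug == drugA]
  inB <- cohort$cases$primaryid %in%
    cohort$exposures$primaryid[cohort$exposures$drug == drugB]
  both <- inA & inB
  t <- contingency(sum(both & shock), sum(both & !shock),
                   sum(!both & shock), sum(!both & !shock))
  data.table::setattr(t, "absent", t$a + t$b == 0)
  t
}

#' Screen co-administered drug pairs for shock association
#'
#' Enumerates every unordered drug pair co-occurring in at least `min_a`
#' target-event reports (the cap bounds the pair combinatorics before any
#' statistic is computed), computes omega with its interval, and ranks by
#' target co-report count `a` descending, then omega descending, then the
#' lexicographic pair. The full qualifying edge list (for network export)
#' is attached as attribute `edges`.
#'
#' @param cohort a `shock_cohort`.
#' @param cfg an [omega_config()].
#' @param top_n number of top-ranked pairs to return (default 30).
#' @param event_scope `"any_shock"` or one preferred term.
#' @return data.table with `drugA`, `drugB`, cells, `omega`, `omega_l95`,
#'   `omega_u95`, `flagged`; at most `top_n` rows.
#' @export
screen_pairs <- function(cohort, cfg = omega_config(), top_n = 30,
                         event_scope = "any_shock") {
  empty <- data.table(drugA = character(0), drugB = character(0),
                      a = numeric(0), b = numeric(0), c = numeric(0),
                      d = numeric(0), omega = numeric(0),
                      omega_l95 = numeric(0), omega_u95 = numeric(0),
                      flagged = logical(0))
  if (nrow(cohort$cases) == 0L) return(empty)
  shock <- scope_flags(cohort, event_scope)
  cases <- data.table(primaryid = cohort$cases$primaryid, is_target = shock)
  expo <- unique(cohort$exposures[, .(primaryid, drug)])

  # pair co-occurrence among target-event reports
  e_shock <- merge(expo, cases[is_target == TRUE, .(primaryid)],
                   by = "primaryid")
  pairs_a <- merge(e_shock, e_shock, by = "primaryid",
                   allow.cartesian = TRUE, suffixes = c("", ".y"))
  pairs_a <- pairs_a[drug < get("drug.y")]
  pairs_a <- pairs_a[, .(a = .N), by = .(drugA = drug, drugB = get("drug.y"))]
  pairs_a <- pairs_a[a >= cfg$min_a]
  if (nrow(pairs_a) == 0L) return(empty)

  # full co-exposure counts for the qualifying pairs only
  qual_drugs <- unique(c(pairs_a$drugA, pairs_a$drugB))
  e_q <- expo[drug %in% qual_drugs]
  co <- merge(e_q, e_q, by = "primaryid", allow.cartesian = TRUE,
              suffixes = c("", ".y"))
  co <- co[drug < get("drug.y")]
  co <- co[, .(n_pair = .N), by = .(drugA = drug, drugB = get("drug.y"))]
  res <- merge(pairs_a, co, by = c("drugA", "drugB"))
  n_total <- nrow(cases)
  n_effect <- sum(shock)
  res[, `:=`(a = as.numeric(a), b = as.numeric(n_pair - a),
             c = as.numeric(n_effect - a),
             d = as.numeric(n_total - n_pair - (n_effect - a)))]
  res <- cbind(res[, .(drugA, drugB, a, b, c, d)],
               omega_stats(res[, .(a, b, c, d)], cfg))
  setorderv(res, c("a", "omega", "drugA", "drugB"),
            order = c(-1L, -1L, 1L, 1L))
  edges <- data.table::copy(res)
  out <- res[seq_len(min(nrow(res), max(0L, top_n)))]
  data.table::setattr(out, "edges", edges)
  out
}
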