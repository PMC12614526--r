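METHOD_NAMES <- c("ROR", "PRR", "BCPNN", "EBGM", "combined_4", "combined_3plus")

#' Evaluate detection methods against planted ground truth
#'
#' A screened drug is condition-positive when it carries a planted
#' single-drug signal with relative rate above 1 (pair signals define pair
#' truth, not single-drug truth). Each method's prediction is its signal
#' flag; `combined_4` requires all four flags, `combined_3plus` requires at
#' least three. Confusion counts always satisfy
#' `tp + fp + tn + fn = number of screened drugs`; rates with a zero
#' denominator are `NA`.
#'
#' @param signals output of [screen_signals()].
#' @param truth list of [planted_signal()] objects (e.g. `sim$truth`).
#' @return data.table with one row per method: `method`, `tp`, `fp`, `tn`,
#'   `fn`, `sensitivity`, `specificity`, `ppv`, `npv`.
#' @export
evaluate_methods <- function(signals, truth) {
  s <- as.data.table(signals)
  pos_drugs <- unique(unlist(lapply(truth, function(x) {
    if (length(x$exposure) == 1L && x$relative_rate > 1) x$exposure else NULL
  })))
  condition <- s$drug %in% pos_drugs
  preds <- list(
    ROR = s$ror_pos, PRR = s$prr_pos, BCPNN = s$bcpnn_pos, EBGM = s$ebgm_pos,
    combined_4 = s$n_positive == 4L,
    combined_3plus = s$n_positive >= 3L)
  rate <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  data.table::rbindlist(lapply(METHOD_NAMES, function(m) {
    p <- preds[[m]]
    tp <- sum(p & condition); fp <- sum(p & !condition)
    fn <- sum(!p & condition); tn <- sum(!p & !condition)
    data.table(method = m, tp = tp, fp = fp, tn = tn, fn = fn,
               sensitivity = rate(tp, tp + fn),
               specificity = rate(tn, tn + fp),
               ppv = rate(tp, tp + fp),
               npv = rate(tn, tn + fn))
  }))
}

#' Aggregate signal drugs by ATC class
#'
#' A signal drug (by default tier `three_method` or better, i.e. at least
#' three positive methods) contributes one count to every ATC class it
#' maps to; unmapped drugs fall into class `"unmapped"`. Shares are
#' percentages of total contributions (so a dual-coded drug counts in both
#' classes and shares still sum to 100 within rounding).
#'
#' @param signals output of [screen_signals()].
#' @param atc_map named character vector drug -> ATC level-1 code, or a
#'   named list for multi-coded drugs; see [demo_atc_map()].
#' @param min_positive tier threshold: minimum `n_positive` to count as a
#'   signal drug (default 3).
#' @return data.table with `atc1`, `n_drugs`, `share` (percent, 2
#'   decimals).
#' @export
aggregate_by_atc <- function(signals, atc_map = demo_atc_map(),
                             min_positive = 3) {
  s <- as.data.table(signals)
  if (nrow(s) == 0L) {
    return(data.table(atc1 = character(0), n_drugs = integer(0),
                      share = numeric(0)))
  }
  sig <- s$drug[s$n_positive >= min_positive]
  if (length(sig) == 0L) {
    return(data.table(atc1 = character(0), n_drugs = integer(0),
                      share = numeric(0)))
  }
  codes <- lapply(sig, function(d) {
    x <- if (d %in% names(atc_map)) atc_map[[d]] else NULL
    if (is.null(x) || all(is.na(x)) || !length(x)) "unmapped" else unique(x)
  })
  contrib <- data.table(atc1 = unlist(codes))
  agg <- contrib[, .(n_drugs = .N), by = atc1]
  agg[, share := percentage(n_drugs, sum(n_drugs), 2)]
  setorderv(agg, c("n_drugs", "atc1"), order = c(-1L, 1L))
  agg[]
}
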