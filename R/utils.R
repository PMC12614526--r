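#' @importFrom data.table data.table as.data.table setDT setorderv := .N .I .SD
#' @importFrom stats rnorm rpois runif quantile sd median setNames
#' @importFrom utils head
NULL

# data.table NSE columns
utils::globalVariables(c(
  ".", "a", "b", "c", "d", "atc1", "caseid", "chi2", "count", "drug",
  "drugA", "drugB", "drug_seq", "drugname", "ebgm05", "ebgm_pos", "fda_dt",
  "ic025", "is_shock", "is_target", "level", "n_drugs", "n_pair",
  "n_positive", "ndrug", "neffect", "nobserved", "nexpected", "ntotal",
  "occp_cod", "omega", "outc_cod", "primaryid", "prr_pos", "pt", "quarter",
  "region", "role_cod", "ror", "ror_l95", "ror_pos", "bcpnn_pos", "serious",
  "sex", "share", "tier", "variable"
))

#' Round half away from zero
#'
#' Decimal rounding in which exact halves move away from zero (so 0.125 at
#' two decimals gives 0.13), the convention used for all printed percentages
#' in this package. Base R's `round()` rounds halves to even instead.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(6.25, 1)  # 6.3, where round(6.25, 1) gives 6.2
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# path of a bundled resource file
pkg_resource <- function(...) {
  system.file("extdata", ..., package = "shockscreen", mustWork = TRUE)
}
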