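#' Percentage with deterministic rounding
#'
#' `100 * count / total`, rounded half-away-from-zero to `decimals` places
#' ([round_half_up()]), the rounding used throughout the descriptive
#' tables. A zero total is undefined and returns `NA` with a warning.
#'
#' @param count nonnegative integer vector.
#' @param total positive integer denominator.
#' @param decimals decimal places (default 2; drug-tier shares use 1).
#' @return numeric vector of percentages.
#' @export
#' @examples
#' percentage(113182, 244030)      # 46.38
#' percentage(79, 847, decimals = 1)  # 9.3
percentage <- function(count, total, decimals = 2) {
  if (any(total == 0)) {
    warning("percentage undefined for total = 0", call. = FALSE)
    return(rep(NA_real_, max(length(count), length(total))))
  }
  if (any(count > total)) stop_config("count must not exceed total")
  round_half_up(100 * count / total, decimals)
}

describe_one <- function(values, variable, decimals = 2) {
  tab <- table(values, useNA = "no")
  total <- length(values)
  data.table(variable = rep(variable, length(tab)),
             level = as.character(names(tab)),
             count = as.integer(tab),
             percent = if (total > 0) {
               percentage(as.integer(tab), total, decimals)
             } else rep(NA_real_, length(tab)))
}

#' Descriptive summary of a case cohort
#'
#' Produces the long-format characteristics table: counts and percentages
#' by gender, age group, reporting year, reporter occupation, region,
#' country and seriousness (each variable's percentages use the full case
#' count as denominator, with unspecified levels included so counts sum to
#' the denominator). Continuous age is summarized over non-missing values
#' as n, mean, SD, median, quartiles (inclusive linear interpolation,
#' `stats::quantile` type 7), min and max, attached as attribute
#' `age_stats` together with the missing count.
#'
#' @param cases the `cases` table of a `shock_cohort` (typically subset to
#'   shock reports for the characteristics table).
#' @return data.table with columns `variable`, `level`, `count`, `percent`;
#'   attributes `denominator` and `age_stats`.
#' @export
summarize_cohort <- function(cases) {
  cases <- as.data.table(cases)
  n <- nrow(cases)
  sex <- cases$sex
  sex[is.na(sex) | !sex %in% c("F", "M")] <- "unspecified"
  pieces <- list(
    describe_one(c("F" = "Female", "M" = "Male",
                   "unspecified" = "Not Specified")[sex], "gender"),
    describe_one(factor(cases$age_group, levels = AGE_GROUP_LEVELS),
                 "age_group"),
    describe_one(cases$reporting_year, "reporting_year"),
    describe_one(c(MD = "Physician", PH = "Pharmacist",
                   OT = "Other health professional")[cases$occp_cod],
                 "reporter"),
    describe_one(cases$region, "region"),
    describe_one(ifelse(is.na(cases$country), "Not Specified", cases$country),
                 "country"),
    describe_one(ifelse(cases$serious, "Serious", "Non-Serious"),
                 "seriousness"))
  out <- data.table::rbindlist(pieces)
  age <- cases$age_years[!is.na(cases$age_years)]
  age_stats <- if (length(age)) {
    q <- unname(quantile(age, c(0.25, 0.5, 0.75), type = 7))
    list(n = length(age), n_missing = n - length(age),
         mean = mean(age), sd = sd(age), q1 = q[1], median = q[2], q3 = q[3],
         min = min(age), max = max(age))
  } else {
    list(n = 0L, n_missing = n, mean = NA_real_, sd = NA_real_,
         q1 = NA_real_, median = NA_real_, q3 = NA_real_,
         min = NA_real_, max = NA_real_)
  }
  data.table::setattr(out, "denominator", n)
  data.table::setattr(out, "age_stats", age_stats)
  out
}
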