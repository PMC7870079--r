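#' @importFrom rlang %||% .data abort warn
#' @importFrom stats median quantile setNames
#' @importFrom utils head tail
NULL

# Day-count arithmetic: all claims rules are integer-day rules, so dates are
# base Date and differences are plain integers.
days_between <- function(from, to) as.integer(as.numeric(to) - as.numeric(from))

as_iso_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x, format = "%Y-%m-%d")
}

#' Round half-up to a fixed number of decimals
#'
#' Table percentages in claims reports are conventionally rounded half-up
#' (2.45 -> 2.5), not to even as [base::round()] does. A small epsilon guards
#' against binary representation of values sitting exactly on a .5 boundary.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(56.0362, 11.6461, 0.05), 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage with the reporting rounding rule
#'
#' Computes `100 * numerator / denominator` rounded half-up to one decimal,
#' the format used throughout the package's rate tables. A zero denominator
#' yields `NA` (an undefined rate is reported as absent, never as 0).
#'
#' @param numerator,denominator nonnegative counts (vectorised).
#' @return numeric vector of percentages on the 0-100 scale, 1 decimal.
#' @export
#' @examples
#' rate_percent(4897, 8739) # 56.0
rate_percent <- function(numerator, denominator) {
  out <- ifelse(denominator > 0, round_half_up(100 * numerator / denominator, 1), NA_real_)
  as.numeric(out)
}

# Age in completed years at `date`, from birth year only. Claims carry birth
# year, so July 1 is the assumed birthday: before July 1 the patient has not
# yet "had" this year's birthday.
age_at <- function(birth_year, date) {
  yr <- as.integer(format(date, "%Y"))
  before_birthday <- format(date, "%m-%d") < "07-01"
  yr - birth_year - as.integer(before_birthday)
}

# min() over a possibly-empty date vector without the base warning
# (dplyr evaluates summarise expressions even for zero-row inputs)
min_date <- function(x) if (length(x) == 0) as.Date(NA) else min(x)

# Days-in-month convention for reporting durations on the month scale.
DAYS_PER_MONTH <- 30.4375

days_to_months <- function(days) days / DAYS_PER_MONTH
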