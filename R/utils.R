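#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published clinical tables
#' conventionally round half away from zero (so 82.25 -> 82.3).  Used for all
#' reported percentages.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * trunc(abs(x) * m + 0.5) / m
}

#' Percentage of a count, rounded half away from zero
#'
#' @param count numerator count.
#' @param total denominator count; must be positive.
#' @param digits decimal places (1 for subgroup shares, 0 for headline
#'   ethnicity shares).
#' @return percentage on the 0-100 scale.
#' @export
percent_of <- function(count, total, digits = 1) {
  stopifnot(total > 0, count >= 0)
  round_half_away(100 * count / total, digits)
}

# Derive a per-task seed from a master seed; kept well below 2^31 so it is
# always a valid R integer seed.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2000000011L
}

# Days-per-year convention used throughout for interval lengths.
DAYS_PER_YEAR <- 365.25

# Truncated-normal sampler via inverse CDF (exact, vectorised).
rtnorm_lower <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  q <- stats::qnorm(u, mean, sd)
  pmax(q, lower) # guard against rounding at the extreme tail
}

`%||%` <- function(a, b) if (is.null(a)) b else a
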