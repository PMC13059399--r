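#' Round half away from zero
#'
#' Decimal rounding with ties going up in absolute value, the convention used
#' when printing report percentages and result tables. `base::round()` uses
#' banker's rounding, which prints 0.575 as 0.57; spontaneous-report summaries
#' conventionally print 0.58.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  # tiny relative nudge guards against binary representations that sit a hair
  # below the .5 boundary (e.g. 2.675 stored as 2.67499...)
  sign(x) * floor(abs(x) * scale * (1 + 1e-12) + 0.5) / scale
}

#' Format a count as a percentage string
#'
#' @param n count in the category.
#' @param total denominator; must be positive (the caller guards empty data).
#' @param digits decimal places (2 matches standard report tables).
#' @return character scalar/vector, fixed decimal places, half-up rounding.
#' @examples
#' percent(4723, 5054) # "93.45"
#' @export
percent <- function(n, total, digits = 2) {
  if (any(total <= 0)) {
    stop("percent() is undefined for total <= 0; caller must guard", call. = FALSE)
  }
  formatC(round_half_up(100 * n / total, digits), format = "f", digits = digits)
}

# quarter arithmetic: a quarter is c(year, q) with q in 1:4
quarter_index <- function(year, q) as.integer(year) * 4L + (as.integer(q) - 1L)

index_to_quarter <- function(idx) {
  idx <- as.integer(idx)
  cbind(year = idx %/% 4L, q = idx %% 4L + 1L)
}

check_quarter <- function(x, what = "quarter") {
  if (length(x) != 2 || !is.numeric(x) || x[2] < 1 || x[2] > 4) {
    stop(what, " must be c(year, quarter) with quarter in 1..4", call. = FALSE)
  }
  invisible(as.integer(x))
}

# "unknown" sentinel used throughout for missing demographics
UNKNOWN <- "unknown"

OUTCOME_LEVELS <- c("death", "life_threatening", "hospitalization", "disability", "other")
ROLE_LEVELS <- c("PS", "SS", "C", "I")
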