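# Exact money arithmetic.
#
# All monetary amounts are whole Iranian Rials (IRR) held in R doubles.
# Every quantity in the model (grand totals included) is far below 2^53,
# so sums and products of whole-Rial amounts are exact.  Probabilities are
# carried as decimal rationals (integer numerator over a power of ten) so
# probability-weighted expectations reduce to integer arithmetic; division
# and rounding happen once, at the end of each computation.

#' Round half away from zero
#'
#' Rounds to the nearest integer with exact halves moving away from zero
#' (so 36,682.5 becomes 36,683 and -0.5 becomes -1).  This is the rounding
#' used throughout for displayed per-patient expectations and for USD
#' conversion; it differs from [base::round()], which rounds halves to even.
#'
#' @param x Numeric vector.
#' @return Numeric vector of integers (as doubles).
#' @export
#' @examples
#' round_half_away(c(36682.5, 2.5, -2.5, 2.4))
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Integer-exact rounded division num/den, half away from zero.
# num and den must be integer-valued doubles, den > 0.
ratio_round_half_away <- function(num, den) {
  s <- ifelse(num < 0, -1, 1)
  a <- abs(num)
  q <- a %/% den
  r <- a - q * den
  s * (q + (2 * r >= den))
}

#' Represent a decimal number as an exact rational
#'
#' Recovers the exact decimal fraction behind a numeric value: `0.105`
#' becomes 105/1000.  Used internally so that adverse-event probabilities
#' (printed to at most three decimals) multiply costs without binary
#' floating-point error.
#'
#' @param x A single finite numeric written with at most `max_digits`
#'   decimal places.
#' @param max_digits Maximum number of decimal places accepted.
#' @return A list with integer-valued components `num` and `den`
#'   (`den` a power of ten) such that `num / den == x` exactly.
#' @export
#' @examples
#' decimal_rational(0.105)
decimal_rational <- function(x, max_digits = 9) {
  stopifnot(is.numeric(x), length(x) == 1L, is.finite(x))
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  n_dec <- if (grepl(".", s, fixed = TRUE)) {
    nchar(sub("^-?[0-9]*\\.", "", s))
  } else {
    0L
  }
  if (n_dec > max_digits) {
    stop("value ", s, " has more than ", max_digits, " decimal places",
         call. = FALSE)
  }
  den <- 10^n_dec
  num <- round(x * den)
  if (abs(num / den - x) > 1e-12 * max(1, abs(x))) {
    stop("value ", s, " is not an exact decimal", call. = FALSE)
  }
  list(num = num, den = den)
}

#' Convert Rials to US dollars
#'
#' Divides by the exchange rate and rounds to the nearest whole dollar,
#' half away from zero.  When the rate is a decimal number the division is
#' performed in exact integer arithmetic (both operands scaled by the
#' rate's denominator), so printed-table conversions are reproduced
#' bit-exactly.
#'
#' @param x Amount(s) in IRR (whole Rials; may be signed for increments).
#' @param rate Exchange rate in IRR per USD; positive.
#' @return Integer USD amount(s), as doubles.
#' @export
#' @examples
#' to_usd(39571037000, 12260)  # 3,227,654
to_usd <- function(x, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) ||
      rate <= 0) {
    stop("`rate` must be a single positive number (IRR per USD)",
         call. = FALSE)
  }
  assert_whole(x, "x")
  r <- decimal_rational(rate)
  ratio_round_half_away(x * r$den, r$num)
}

# ---- validation helpers ----------------------------------------------------

assert_whole <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x != floor(x))) {
    stop("`", what, "` must be a whole number of Rials", call. = FALSE)
  }
  invisible(x)
}

assert_money <- function(x, what) {
  assert_whole(x, what)
  if (any(x < 0)) {
    stop("`", what, "` must be a non-negative whole number of Rials",
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, what, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != floor(x) ||
      x < min) {
    stop("`", what, "` must be an integer >= ", min, call. = FALSE)
  }
  invisible(x)
}

assert_nonneg <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop("`", what, "` must be a single non-negative number", call. = FALSE)
  }
  invisible(x)
}

assert_prob <- function(x, what = "probability") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop("`", what, "` must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}
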