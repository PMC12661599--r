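#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when formatting report tables.
#' Base R's `round()` rounds half to even, which does not reproduce printed
#' table cells such as 6394.5 -> 6395.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (may be negative).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(6394.5)   # 6395 (round() would give 6394)
#' round_half_up(2.345, 2) # 2.35
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values stored just below .5 (binary
  # representation of decimals) still round up
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Format pounds as millions
#'
#' Presentation helper: scales GBP to millions and rounds half-up.
#'
#' @param x GBP amounts.
#' @param digits Decimal places kept after scaling (default 2, e.g. 86.98).
#' @return Numeric vector in units of GBP millions.
#' @export
gbp_millions <- function(x, digits = 2) {
  round_half_up(x / 1e6, digits)
}

#' Construct a money interval
#'
#' A low/high pair of GBP amounts, the package's representation of ranged
#' costs such as the NICE willingness-to-pay band monetisation.
#'
#' @param low,high GBP amounts with `low <= high` (element-wise).
#' @return A one-row (or n-row) tibble with columns `low` and `high`.
#' @examples
#' money_interval(238240000, 357360000)
#' @export
money_interval <- function(low, high) {
  stopifnot(is.numeric(low), is.numeric(high))
  if (any(high < low)) {
    stop("money interval requires low <= high", call. = FALSE)
  }
  tibble::tibble(low = as.numeric(low), high = as.numeric(high))
}

#' Component-wise sum of money intervals
#'
#' @param ... Money intervals (tibbles with `low`/`high`), each one row.
#' @return A one-row money interval whose bounds are the component sums.
#' @examples
#' interval_sum(money_interval(1, 2), money_interval(10, 20))
#' @export
interval_sum <- function(...) {
  parts <- list(...)
  stopifnot(length(parts) > 0)
  for (p in parts) stopifnot(is.data.frame(p), all(c("low", "high") %in% names(p)))
  money_interval(
    low = sum(vapply(parts, function(p) sum(p$low), numeric(1))),
    high = sum(vapply(parts, function(p) sum(p$high), numeric(1)))
  )
}

# shared input check: a single non-negative finite number
check_scalar_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
    stop(sprintf("`%s` must be a single non-negative number", name), call. = FALSE)
  }
  invisible(x)
}
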