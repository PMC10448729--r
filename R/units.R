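#' Convert between percent and fractional MRD scales
#'
#' Clinical flow-cytometry reports mix two scales for the same quantity: a
#' percentage of nucleated cells (e.g. a detection limit printed as 0.00019)
#' and a dimensionless fraction in scientific notation (the same limit,
#' 1.9e-6). All mrdflow internals work on the fractional scale; these helpers
#' convert at input/output boundaries.
#'
#' @param x_percent Non-negative numeric vector on the percent scale.
#' @param x Non-negative numeric vector on the fractional scale.
#'
#' @return Numeric vector on the other scale. The round trip
#'   `fraction_to_percent(percent_to_fraction(x))` is exact to machine
#'   precision.
#' @examples
#' percent_to_fraction(0.00019) # 1.9e-06
#' fraction_to_percent(5.7e-06) # 0.00057
#' @export
percent_to_fraction <- function(x_percent) {
  check_non_negative(x_percent, "x_percent")
  x_percent / 100
}

#' @rdname percent_to_fraction
#' @export
fraction_to_percent <- function(x) {
  check_non_negative(x, "x")
  x * 100
}

# shared argument checks ------------------------------------------------------

check_non_negative <- function(x, name) {
  if (!is.numeric(x)) {
    stop(sprintf("`%s` must be numeric.", name), call. = FALSE)
  }
  if (any(x < 0, na.rm = TRUE)) {
    stop(sprintf("`%s` must be non-negative.", name), call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(x <= 0, na.rm = TRUE)) {
    stop(sprintf("`%s` must be positive.", name), call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  if (!is.numeric(x) || any(x < 0 | x > 1, na.rm = TRUE)) {
    stop(sprintf("`%s` must lie in [0, 1].", name), call. = FALSE)
  }
  invisible(x)
}
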