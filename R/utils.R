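#' Round half away from zero
#'
#' Presentation rounding used throughout the package: ties round up (0.05 ->
#' 0.1), unlike base R's round-half-even. Applied only when values are
#' reported or banded, never inside supply arithmetic.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1, the precision at which
#'   supply estimates are reported).
#' @return Numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(1.45, 1.55, 2.25))
#' @export
round_half_up <- function(x, digits = 1) {
  stopifnot(is.numeric(x), is.numeric(digits), length(digits) == 1)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# shared validation helpers ---------------------------------------------

assert_scalar_number <- function(x, name, min = NULL, max = NULL) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name),
          class = "vitd_validation_error")
  }
  if (!is.null(min) && x < min) {
    abort(sprintf("`%s` must be >= %s (got %s).", name, min, x),
          class = "vitd_validation_error")
  }
  if (!is.null(max) && x > max) {
    abort(sprintf("`%s` must be <= %s (got %s).", name, max, x),
          class = "vitd_validation_error")
  }
  invisible(x)
}

assert_fraction <- function(x, name) {
  assert_scalar_number(x, name, min = 0, max = 1)
}

assert_has_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing mandatory column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "vitd_format_error")
  }
  invisible(df)
}
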