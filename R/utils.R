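#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; result tables in this package use
#' conventional half-up rounding so that printed percentages match how such
#' tables are usually rendered (e.g. 24/41 of 100 -> 58.54).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small eps guards against binary representation of exact .5 boundaries
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# stop() with sprintf-style formatting, no call in the condition
.err <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.msg <- function(fmt, ...) message(sprintf(fmt, ...))
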