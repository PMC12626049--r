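#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 72.85 -> 72.9 at one
#' decimal), matching how composite percentages and index values are printed.
#' Base [round()] uses round-half-to-even, which would print 0.5-boundary
#' values differently.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(72.85, 1)
#' round_half_up(8.47, 1)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: abort with a classed condition so callers/tests can be specific
pil_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "pilappraise_error"))
}
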