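#' Round half away from zero
#'
#' Display rounding used throughout the package: ties are rounded away from
#' zero (so 0.125 -> 0.13 and -0.125 -> -0.13), unlike [base::round()]'s
#' round-half-to-even. Internal computations always keep full precision;
#' this is applied only when values are formatted for output.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(2.675, 2)   # 2.68
#' round_half_up(-0.125, 2)  # -0.13
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# format p-values the way clinical tables print them: 3 dp, "<0.001" below
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", sprintf("%.3f", round_half_up(p, 3)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x == trunc(x)
}

stop_pvic <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "pvic_error")))
}
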