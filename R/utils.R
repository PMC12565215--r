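#' Round half away from zero
#'
#' Commercial rounding used for all rendered statistics: exact halves move
#' away from zero (so -0.8125 renders as -0.813 at 3 decimals), unlike base
#' \code{round()}, which rounds halves to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Format a number trimming trailing zeros ("5.00" -> "5", "3.50" -> "3.5").
fmtTrim <- function(x, digits = 4) {
  s <- formatC(roundHalfUp(x, digits), format = "f", digits = digits)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

# Stop with a classed validation error so callers (and the CLI) can map
# validation failures to a distinct exit code.
validationError <- function(msg) {
  stop(errorCondition(msg, class = c("mycoGraze_validation_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direction / effect symbols used in conclusion codes.
SYM_UP <- "\u2191"
SYM_FLAT <- "|"
SYM_DOWN <- "\u2193"
EFFECT_SYMBOLS <- c(
  negligible = "-", minor = "+", moderate = "++", large = "+++"
)
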