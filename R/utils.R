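#' @keywords internal
"_PACKAGE"

## Condition helpers. Three error classes are used throughout:
##   postrisk_format_error     -- malformed input files
##   postrisk_validation_error -- well-formed input violating an invariant
##   postrisk_domain_error     -- arguments outside an operation's domain
abort_format <- function(msg) {
  stop(structure(class = c("postrisk_format_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_validation <- function(msg) {
  stop(structure(class = c("postrisk_validation_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_domain <- function(msg) {
  stop(structure(class = c("postrisk_domain_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

## Diagnostics go to stderr, never to stdout, so rendered tables stay clean.
risk_log <- function(level = c("info", "warn"), msg) {
  level <- match.arg(level)
  message(sprintf("[%s] %s", level, msg))
}

## Unicode NFC normalization for level labels: table labels carry en-dashes
## and the >= sign, which can arrive in decomposed form from other tools.
nfc <- function(x) stringi::stri_trans_nfc(enc2utf8(as.character(x)))

#' Round half-up
#'
#' Decimal rounding with ties going away from zero (the convention used by
#' the printed tables), unlike [round()]'s round-half-even. A tiny
#' pre-rounding at 9 decimals absorbs binary floating-point fuzz so that
#' values such as 0.5 stored as 0.49999... still round up.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half-up at `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  sign(x) * floor(round(abs(x) * s, 9) + 0.5) / s
}

#' Format a fraction as a percentage string
#'
#' Renders a proportion on the percent scale with round-half-up at the
#' requested precision, optionally trimming trailing zeros (the style of the
#' published risk table, which prints "6.3" and "15.4" rather than "6.30").
#'
#' @param x numeric vector of fractions in \[0, 1\].
#' @param decimals integer decimal places on the percent scale.
#' @param trim drop trailing zeros (and a trailing decimal point)?
#' @param symbol append a percent sign?
#' @return character vector.
#' @examples
#' format_percent(0.02126, 1)            # "2.1%"
#' format_percent(0.4338, 2, symbol = FALSE)  # "43.38"
#' @export
format_percent <- function(x, decimals = 1, trim = FALSE, symbol = TRUE) {
  if (any(x < 0 | x > 1, na.rm = TRUE))
    abort_domain("format_percent() expects fractions in [0, 1]")
  out <- sprintf(paste0("%.", decimals, "f"), round_half_up(x * 100, decimals))
  if (trim && decimals > 0) {
    out <- sub("0+$", "", out)
    out <- sub("\\.$", "", out)
  }
  if (symbol) out <- paste0(out, "%")
  out
}
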