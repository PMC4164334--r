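#' Percentage of a total, rounded for reporting
#'
#' @param count numeric numerator.
#' @param total numeric denominator, > 0.
#' @param digits decimal places to round to.
#' @return `100 * count / total`, rounded.
#' @examples
#' percentOf(75, 2213, digits = 1)  # 3.4
#' @export
percentOf <- function(count, total, digits = 2L) {
  if (any(total <= 0)) stop("total must be positive")
  round(100 * count / total, digits)
}

## Phred+33 encoding: integer vector -> one quality string
encodeQuality <- function(q) {
  intToUtf8(q + 33L)
}

decodeQuality <- function(s) {
  lapply(s, function(x) utf8ToInt(x) - 33L)
}

## split "A,B,C" family id cells; NA or "" -> character(0)
splitFamilyIds <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), ",", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}
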