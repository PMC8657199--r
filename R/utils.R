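# Shared small helpers.

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with exact halves rounded up (away
#' from zero), the convention used by the package's printed percentage
#' tables. Base R's [round()] rounds half to even, which disagrees with
#' conventionally typeset tables on exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(45.85, 1) # 45.9, where round() gives 45.8
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  # small epsilon guards against binary representation of exact halves
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percentage of a count over a denominator, rounded half-up
#'
#' @param n numerator count(s).
#' @param denom denominator.
#' @param digits decimal places (default 1, the usual table precision).
#' @return numeric percentage(s) on the 0-100 scale.
#' @examples
#' pct_half_up(139, 303) # 45.9
#' @export
pct_half_up <- function(n, denom, digits = 1) {
  round_half_up(100 * n / denom, digits = digits)
}

# stop with a classed condition, no call
vs_abort <- function(msg, class) {
  rlang::abort(msg, class = c(class, "vigisignal_error"))
}

vs_warn <- function(msg, class) {
  rlang::warn(msg, class = c(class, "vigisignal_warning"))
}

# collapse a character vector for messages
oxford <- function(x, max = 10) {
  if (length(x) > max) x <- c(head(x, max), sprintf("... (%d more)", length(x) - max))
  paste(x, collapse = ", ")
}
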