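# Small shared helpers.

#' Root mean square
#'
#' Standard 2-norm scaled by the square root of the length, i.e.
#' `sqrt(mean(x^2))`. Used throughout the screening aggregations.
#'
#' @param x Numeric vector.
#' @return A non-negative scalar.
#' @export
rms <- function(x) {
  sqrt(mean(x^2))
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero (the convention
#' used for reported reduction percentages), unlike [base::round()]'s
#' round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pf <- function(...) stop(..., call. = FALSE)

warn_pf <- function(...) warning(..., call. = FALSE)
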