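# Stimulus protocols: ordered (VO2, VCO2) exercise levels applied as
# consecutive, equidistant, incremental steps.

#' Define a stimulus protocol
#'
#' An exercise protocol is an ordered sequence of stimulus levels, each a
#' pair of oxygen uptake (VO2) and carbon dioxide output (VCO2) in L/min,
#' applied as successive steps of equal duration. Steady-state values are
#' read as the signal average over the final `settle_window` seconds of each
#' level.
#'
#' @param vo2 Numeric vector of VO2 values (L/min), one per level.
#' @param vco2 Numeric vector of VCO2 values (L/min), strictly increasing.
#' @param step_duration Duration of each level in seconds (default 3000 s,
#'   long enough for all variables to settle).
#' @param settle_window Averaging window at the end of each level in seconds
#'   (default 60 s, the last minute).
#' @return A `pf_protocol` object.
#' @export
stimulus_protocol <- function(vo2, vco2, step_duration = 3000,
                              settle_window = 60) {
  if (length(vo2) != length(vco2) || length(vco2) < 1L) {
    stop_pf("vo2 and vco2 must be non-empty vectors of equal length")
  }
  if (any(diff(vco2) <= 0)) {
    stop_pf("protocol levels must be strictly increasing in VCO2")
  }
  if (!(step_duration >= settle_window && settle_window > 0)) {
    stop_pf("need step_duration >= settle_window > 0")
  }
  structure(list(vo2 = as.numeric(vo2), vco2 = as.numeric(vco2),
                 step_duration = step_duration,
                 settle_window = settle_window),
            class = "pf_protocol")
}

#' Number of levels in a protocol
#' @param protocol A `pf_protocol`.
#' @return Integer count of stimulus levels.
#' @export
n_levels <- function(protocol) length(protocol$vco2)

#' @export
print.pf_protocol <- function(x, ...) {
  cat("Stimulus protocol:", n_levels(x), "levels\n")
  print(data.frame(level = seq_along(x$vco2), vo2 = x$vo2, vco2 = x$vco2))
  cat("step duration:", x$step_duration, "s; settle window:",
      x$settle_window, "s\n")
  invisible(x)
}
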