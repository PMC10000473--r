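# Parameter registry: one row per model parameter, carrying its nominal
# value, role class, subsystem, mechanism tag, bounds and flags.

PF_ROLES <- c("time_constant", "conversion", "covariate",
              "initial_value", "gain_threshold")

#' Define a single model parameter
#'
#' Builds a one-row parameter specification. Parameters are classified by the
#' part they play in the model: `time_constant` (transient response),
#' `conversion` (unit equivalences), `covariate` (simulation conditions taken
#' from the data: environment and subject characteristics), `initial_value`
#' (integrator initial states) and `gain_threshold` (gains and thresholds
#' that modulate or saturate model mechanisms -- the only pool from which
#' fitted parameters are drawn).
#'
#' @param name Parameter identifier.
#' @param nominal Finite nominal value in model units.
#' @param role One of `"time_constant"`, `"conversion"`, `"covariate"`,
#'   `"initial_value"`, `"gain_threshold"`.
#' @param subsystem Subsystem the parameter belongs to (one of the
#'   model-declared set).
#' @param unit Unit string (documentation only).
#' @param mechanism Optional mechanism tag linking the parameter to a
#'   stimulus-related regulation mechanism (e.g. `"chemoreflex"`).
#' @param activity Regulatory activity within the mechanism (e.g.
#'   `"central CO2 drive"`). Required when `mechanism` is given.
#' @param lower,upper Default evaluation-range bounds as signed fractions of
#'   the nominal value (defaults -0.30 / +0.30).
#' @param fixed Logical; `TRUE` for parameters pinned by standardization.
#' @param excluded Logical; `TRUE` for clinically non-modifiable parameters
#'   that must never enter any candidate set.
#' @return A one-row data frame.
#' @export
param_spec <- function(name, nominal, role, subsystem, unit = "",
                       mechanism = NA_character_, activity = NA_character_,
                       lower = -0.30, upper = 0.30,
                       fixed = FALSE, excluded = FALSE) {
  role <- match.arg(role, PF_ROLES)
  if (!is.finite(nominal)) {
    stop_pf("parameter '", name, "': nominal value must be finite")
  }
  if (!fixed && lower >= upper) {
    stop_pf("parameter '", name, "': lower bound fraction must be < upper")
  }
  if (!is.na(mechanism) && is.na(activity)) {
    stop_pf("parameter '", name, "': mechanism tag requires an activity label")
  }
  data.frame(name = name, nominal = nominal, role = role,
             subsystem = subsystem, unit = unit,
             mechanism = mechanism, activity = activity,
             lower = lower, upper = upper,
             fixed = fixed, excluded = excluded,
             stringsAsFactors = FALSE)
}

#' Assemble a parameter registry
#'
#' Binds [param_spec()] rows into a validated registry (class
#' `pf_registry`).
#'
#' @param ... One-row data frames from [param_spec()], or a single list of
#'   them.
#' @return A `pf_registry` data frame.
#' @export
parameter_registry <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && is.list(specs[[1L]]) &&
      !is.data.frame(specs[[1L]])) {
    specs <- specs[[1L]]
  }
  reg <- do.call(rbind, specs)
  if (anyDuplicated(reg$name)) {
    stop_pf("duplicated parameter names in registry: ",
            paste(unique(reg$name[duplicated(reg$name)]), collapse = ", "))
  }
  rownames(reg) <- reg$name
  class(reg) <- c("pf_registry", "data.frame")
  reg
}

#' Nominal parameter vector of a registry
#'
#' @param registry A `pf_registry`.
#' @return Named numeric vector of nominal values.
#' @export
nominal_params <- function(registry) {
  stats::setNames(registry$nominal, registry$name)
}

#' Write / read a registry as JSON
#'
#' The registry round-trips losslessly through a JSON array of records.
#'
#' @param registry A `pf_registry`.
#' @param path File path.
#' @return `read_registry_json` returns a `pf_registry`.
#' @export
write_registry_json <- function(registry, path) {
  jsonlite::write_json(as.data.frame(registry), path,
                       auto_unbox = FALSE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_registry_json
#' @export
read_registry_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  for (col in c("mechanism", "activity")) {
    df[[col]] <- as.character(df[[col]])
  }
  parameter_registry(lapply(seq_len(nrow(df)), function(i) {
    do.call(param_spec, as.list(df[i, , drop = FALSE]))
  }))
}
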