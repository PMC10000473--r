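# Simulator contract. A model is a `pf_model` object exposing:
#   - registry: a pf_registry of every parameter with roles and bounds;
#   - variables: data frame (name, unit, subsystem) of observed outputs;
#   - related: named list mapping each subsystem to the subsystems directly
#     related to it (controller <-> controlled system adjacency);
#   - methods simulate_steady_state() and simulate_transient().

#' Simulate the steady-state response of a model
#'
#' Returns the steady-state value of every observed variable at every level
#' of the stimulus protocol. For fixed-point models this is the exact fixed
#' point per level; for models integrated in time it is the mean over the
#' final settle window of each level. Deterministic given `(params,
#' protocol)`.
#'
#' @param model A `pf_model`.
#' @param params Full named parameter vector (every registry entry present).
#'   Defaults to the registry nominals.
#' @param protocol A `pf_protocol`.
#' @return A `pf_steady` object: matrix `values` (variables x levels) plus
#'   the provenance (`params`, `protocol`).
#' @export
simulate_steady_state <- function(model, params = NULL, protocol) {
  UseMethod("simulate_steady_state")
}

#' Simulate the transient response of a model
#'
#' Integrates the model through the protocol's successive steps and samples
#' every observed variable at `sample_dt` intervals. Each variable relaxes
#' from its pre-step state toward the steady state of the active level.
#'
#' @inheritParams simulate_steady_state
#' @param sample_dt Sampling interval in seconds.
#' @param init `"steady"` starts every variable at the steady state of the
#'   first level; `"params"` starts the variables with declared
#'   `initial_value` parameters at those values instead.
#' @return A `pf_transient`: matrix `values` (variables x time points) with
#'   a `time` vector attribute.
#' @export
simulate_transient <- function(model, params = NULL, protocol, sample_dt = 1,
                               init = c("steady", "params")) {
  UseMethod("simulate_transient")
}

#' Observed variable names of a model
#'
#' @param model A `pf_model`.
#' @param fitting If `TRUE`, return the subset used for screening and
#'   fitting (excludes variables that are deterministic combinations of
#'   others, such as tidal volume VT = VE/BF); otherwise the full validation
#'   set.
#' @return Character vector of variable names.
#' @export
model_variables <- function(model, fitting = FALSE) {
  v <- model$variables$name
  if (fitting) setdiff(v, model$derived_variables) else v
}

#' Complete a parameter vector against a model's registry
#'
#' Fills unspecified parameters with their registry nominals; errors on
#' names the registry does not declare.
#'
#' @param model A `pf_model`.
#' @param params Named numeric vector of overrides, or `NULL`.
#' @return Full named parameter vector.
#' @export
full_params <- function(model, params = NULL) {
  full <- nominal_params(model$registry)
  if (is.null(params)) return(full)
  bad <- setdiff(names(params), names(full))
  if (length(bad)) {
    stop_pf("unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  full[names(params)] <- params
  full
}

new_pf_steady <- function(values, params, protocol) {
  stopifnot(is.matrix(values), ncol(values) == n_levels(protocol))
  structure(list(values = values, params = params, protocol = protocol),
            class = "pf_steady")
}

#' @export
print.pf_steady <- function(x, ...) {
  cat("Steady-state response (", nrow(x$values), " variables x ",
      ncol(x$values), " levels)\n", sep = "")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
print.pf_model <- function(x, ...) {
  cat("Model:", x$name, "\n")
  cat(nrow(x$registry), "parameters;", nrow(x$variables),
      "observed variables\n")
  cat("roles:", paste(names(table(x$registry$role)),
                      table(x$registry$role), collapse = ", "), "\n")
  invisible(x)
}

#' Analytic first-order step response
#'
#' Value at times `t` of a variable relaxing from `y0` toward `yss` with
#' time constant `tau`: `yss + (y0 - yss) * exp(-t / tau)`.
#'
#' @param t Times (seconds, from the step onset).
#' @param y0 Initial value.
#' @param yss Target steady-state value.
#' @param tau Time constant in seconds (> 0).
#' @return Numeric vector of responses.
#' @export
first_order_response <- function(t, y0, yss, tau) {
  stopifnot(tau > 0)
  yss + (y0 - yss) * exp(-t / tau)
}

#' Write a steady-state response as tidy text
#'
#' Columns: level, variable, value (tab-separated).
#'
#' @param response A `pf_steady`.
#' @param path Output file path.
#' @export
write_steady_state <- function(response, path) {
  df <- data.frame(
    level = rep(seq_len(ncol(response$values)), each = nrow(response$values)),
    variable = rep(rownames(response$values), ncol(response$values)),
    value = as.vector(response$values)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
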