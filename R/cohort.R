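# Synthetic cohort generator: experimental-style steady-state datasets with
# known ground truth. Subjects differ from the cohort truth through
# multiplicative lognormal variation of the gain/threshold parameters;
# observations carry multiplicative lognormal measurement noise. Both noise
# sources are positive and scale with magnitude, matching the behaviour of
# physiological measurements.

#' Define a cohort noise model
#'
#' @param inter_subject_cv Coefficient of variation of subject-level true
#'   gain/threshold parameters around the cohort truth (fraction, >= 0).
#' @param measurement_cv Coefficient of variation of the multiplicative
#'   observation noise (fraction, >= 0).
#' @return A `pf_noise` object. Both CVs at 0 reproduce the cohort-truth
#'   simulation exactly.
#' @export
noise_model <- function(inter_subject_cv = 0.10, measurement_cv = 0.05) {
  stopifnot(inter_subject_cv >= 0, measurement_cv >= 0)
  structure(list(inter_subject_cv = inter_subject_cv,
                 measurement_cv = measurement_cv,
                 distribution = "lognormal"),
            class = "pf_noise")
}

# Lognormal multiplicative factors with mean exactly 1 and the requested CV.
rln_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic steady-state cohort
#'
#' Simulates `n_subjects` subjects at every level of `protocol`. Each
#' subject's true parameter vector is the cohort truth with lognormal
#' inter-subject variation applied to the (non-excluded) gain/threshold
#' parameters; observed values are the subject's steady-state simulation
#' times lognormal measurement noise. Each subject receives an anaerobic
#' threshold (AT, as a VCO2 value) drawn uniformly between the
#' third-highest and highest protocol levels. Subject random streams are
#' derived from the master seed by fixed offsets, so extending the cohort
#' never reshuffles earlier subjects.
#'
#' @param model A `pf_model`.
#' @param true_params Cohort-truth parameter vector (named; missing entries
#'   default to registry nominals).
#' @param protocol A `pf_protocol`.
#' @param n_subjects Number of subjects (>= 1).
#' @param noise A [noise_model()].
#' @param seed Master integer seed.
#' @param resample_cap Maximum resampling attempts per subject when a drawn
#'   parameter vector fails to simulate.
#' @return A `pf_dataset`: tidy `observations` (subject, level, vco2,
#'   variable, value), `covariates`, per-subject `at` (VCO2 at AT),
#'   ground-truth parameter vectors (`true_params`, `subject_params`) and
#'   `noise_meta`.
#' @export
generate_cohort <- function(model, true_params = NULL, protocol,
                            n_subjects, noise = noise_model(), seed,
                            resample_cap = 10L) {
  stopifnot(n_subjects >= 1)
  truth <- full_params(model, true_params)
  reg <- model$registry
  vary <- reg$name[reg$role == "gain_threshold" & !reg$excluded]
  k <- n_levels(protocol)
  vars <- model_variables(model)
  # AT window: the 6th..8th levels of the 8-step protocol; never below the
  # first exercise level for short protocols
  at_lo <- protocol$vco2[max(min(k, 2L), k - 2L)]
  at_hi <- protocol$vco2[k]

  obs <- vector("list", n_subjects)
  subj_params <- matrix(NA_real_, nrow = length(truth), ncol = n_subjects,
                        dimnames = list(names(truth), NULL))
  at <- numeric(n_subjects)
  for (s in seq_len(n_subjects)) {
    # fixed per-subject stream offset from the master seed
    set.seed(as.integer((seed + 7919 * s) %% .Machine$integer.max))
    sim <- NULL
    for (try in seq_len(resample_cap)) {
      ps <- truth
      ps[vary] <- ps[vary] * rln_factor(length(vary),
                                        noise$inter_subject_cv)
      sim <- tryCatch(simulate_steady_state(model, ps, protocol),
                      error = function(e) NULL)
      if (!is.null(sim)) break
    }
    if (is.null(sim)) {
      stop_pf("subject ", s, ": simulation failed after ", resample_cap,
              " resampling attempts")
    }
    subj_params[, s] <- ps
    at[s] <- stats::runif(1, at_lo, at_hi)
    y <- sim$values[vars, , drop = FALSE]
    noise_fac <- matrix(rln_factor(length(y), noise$measurement_cv),
                        nrow = nrow(y))
    yobs <- y * noise_fac
    obs[[s]] <- data.frame(
      subject = sprintf("S%03d", s),
      level = rep(seq_len(k), each = length(vars)),
      vco2 = rep(protocol$vco2, each = length(vars)),
      variable = rep(vars, k),
      value = as.vector(yobs),
      stringsAsFactors = FALSE
    )
  }
  covr <- reg$name[reg$role == "covariate"]
  structure(list(
    observations = do.call(rbind, obs),
    covariates = as.list(truth[covr]),
    at = stats::setNames(at, sprintf("S%03d", seq_len(n_subjects))),
    true_params = truth,
    subject_params = subj_params,
    protocol = protocol,
    variables = vars,
    noise_meta = list(inter_subject_cv = noise$inter_subject_cv,
                      measurement_cv = noise$measurement_cv,
                      distribution = noise$distribution,
                      seed = seed)
  ), class = "pf_dataset")
}

#' Restrict a dataset to each subject's anaerobic threshold
#'
#' Removes, per subject, the observations at levels whose VCO2 exceeds that
#' subject's AT. No other values change. An empty result is allowed and
#' flagged with a warning.
#'
#' @param dataset A `pf_dataset` with per-subject `at` values.
#' @return The truncated `pf_dataset`.
#' @export
truncate_at_AT <- function(dataset) {
  if (is.null(dataset$at)) stop_pf("dataset carries no AT values")
  keep <- dataset$observations$vco2 <=
    dataset$at[dataset$observations$subject] + 1e-12
  dataset$observations <- dataset$observations[keep, , drop = FALSE]
  if (nrow(dataset$observations) == 0L) {
    warn_pf("AT truncation removed every observation")
  }
  dataset
}

#' Cohort-mean observation matrix
#'
#' Across-subject mean of the observed values at each (variable, level)
#' pair, as a variables x levels matrix aligned with the protocol. Used as
#' the fitting reference ("average measurements of all registered
#' subjects").
#'
#' @param dataset A `pf_dataset`.
#' @param variables Optional variable subset (default: all dataset
#'   variables, in dataset order).
#' @return Numeric matrix, variables x levels.
#' @export
cohort_means <- function(dataset, variables = NULL) {
  variables <- variables %||% dataset$variables
  obs <- dataset$observations
  k <- n_levels(dataset$protocol)
  m <- matrix(NA_real_, nrow = length(variables), ncol = k,
              dimnames = list(variables, NULL))
  agg <- stats::aggregate(value ~ variable + level, data = obs, FUN = mean)
  for (r in seq_len(nrow(agg))) {
    if (agg$variable[r] %in% variables) {
      m[agg$variable[r], agg$level[r]] <- agg$value[r]
    }
  }
  m
}

#' Write / read a dataset as tidy text plus a JSON sidecar
#'
#' Observations go to a tab-separated file (subject, level, vco2, variable,
#' value); covariates, AT values, protocol, ground truth and noise metadata
#' go to `<path>.json`.
#'
#' @param dataset A `pf_dataset`.
#' @param path Path of the tabular file.
#' @return `read_dataset` returns the `pf_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.table(dataset$observations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(covariates = dataset$covariates,
               at = as.list(dataset$at),
               true_params = as.list(dataset$true_params),
               subject_params = dataset$subject_params,
               protocol = unclass(dataset$protocol),
               variables = dataset$variables,
               noise_meta = dataset$noise_meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  obs <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  side <- jsonlite::fromJSON(paste0(path, ".json"))
  proto <- stimulus_protocol(side$protocol$vo2, side$protocol$vco2,
                             side$protocol$step_duration,
                             side$protocol$settle_window)
  structure(list(
    observations = obs,
    covariates = side$covariates,
    at = unlist(side$at),
    true_params = unlist(side$true_params),
    subject_params = side$subject_params,
    protocol = proto,
    variables = side$variables,
    noise_meta = side$noise_meta
  ), class = "pf_dataset")
}

#' @export
print.pf_dataset <- function(x, ...) {
  cat("Synthetic cohort:", length(unique(x$observations$subject)),
      "subjects,", length(x$variables), "variables,",
      n_levels(x$protocol), "levels\n")
  cat("noise: inter-subject CV", x$noise_meta$inter_subject_cv,
      "; measurement CV", x$noise_meta$measurement_cv,
      "; seed", x$noise_meta$seed, "\n")
  invisible(x)
}
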