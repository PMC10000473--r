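# Validation: prediction error (median absolute relative error per
# variable, averaged over variables, in percent), percent change from
# rest, settling time against a +/-5% band, and stage-wise comparisons.

#' Prediction error of a steady-state response
#'
#' Per variable, the median over all surviving (subject, level) pairs of
#' the absolute relative error between each subject's observation and the
#' single cohort-level simulation; the overall PE is the mean over
#' variables, times 100%. The median is taken jointly over subject x
#' level pairs.
#'
#' @param dataset A `pf_dataset` (typically truncated at each subject's
#'   AT).
#' @param response A `pf_steady` simulated at the dataset's protocol, or a
#'   variables x levels matrix.
#' @param variables Variables to score (default: all dataset variables).
#' @return List: `pe` (percent), `per_variable` (percent, named),
#'   `per_subsystem` (optional; see [validate_model()]), `n_pairs`.
#' @export
prediction_error <- function(dataset, response, variables = NULL) {
  variables <- variables %||% dataset$variables
  ysim <- if (inherits(response, "pf_steady")) response$values else response
  obs <- dataset$observations
  obs <- obs[obs$variable %in% variables, , drop = FALSE]
  obs$sim <- ysim[cbind(match(obs$variable, rownames(ysim)), obs$level)]
  obs$rel <- abs(obs$value - obs$sim) / abs(obs$value)
  med <- tapply(obs$rel, factor(obs$variable, levels = variables), stats::median)
  dropped <- variables[is.na(med)]
  if (length(dropped)) {
    warn_pf("variable(s) with no surviving (subject, level) pairs ",
            "excluded from PE: ", paste(dropped, collapse = ", "))
  }
  med <- med[!is.na(med)]
  list(pe = mean(med) * 100,
       per_variable = med * 100,
       n_pairs = nrow(obs))
}

# Per-subject PE (mean over the group's variables of the median over the
# subject's levels), used for subsystem tables and stage comparisons.
per_subject_pe <- function(dataset, response, variables) {
  ysim <- if (inherits(response, "pf_steady")) response$values else response
  obs <- dataset$observations
  obs <- obs[obs$variable %in% variables, , drop = FALSE]
  obs$sim <- ysim[cbind(match(obs$variable, rownames(ysim)), obs$level)]
  obs$rel <- abs(obs$value - obs$sim) / abs(obs$value)
  med <- stats::aggregate(rel ~ subject + variable, data = obs,
                          FUN = stats::median)
  out <- tapply(med$rel, med$subject, mean) * 100
  out[sort(names(out))]
}

#' Percent change of a series from its rest baseline
#'
#' `(y(t) - y0) / y0` per sample; 0 at the baseline itself.
#'
#' @param series Numeric vector of samples.
#' @param baseline Rest value (nonzero).
#' @return Numeric vector of proportional changes.
#' @export
percent_change_from_rest <- function(series, baseline) {
  if (baseline == 0) stop_pf("zero baseline in percent change")
  (series - baseline) / baseline
}

#' Settling time of a step response
#'
#' Time elapsed from the stimulus onset until the response enters, and
#' permanently stays inside, a +/-5% tolerance band around its final
#' value ("final entry" semantics). If the final value is (numerically)
#' zero the band falls back to 5% of the step magnitude, with a warning.
#'
#' @param series Numeric samples.
#' @param time Sample times (seconds), same length as `series`.
#' @param t_onset Stimulus onset time.
#' @param final_value Final value the response settles to (default: the
#'   last sample).
#' @param band Tolerance band as a fraction of `|final_value|` (default
#'   0.05).
#' @return Settling time in seconds relative to onset; `NA` (with a
#'   warning) if the band is never permanently entered.
#' @export
settling_time <- function(series, time, t_onset = 0, final_value = NULL,
                          band = 0.05) {
  stopifnot(length(series) == length(time))
  keep <- time >= t_onset
  y <- series[keep]
  t <- time[keep]
  final_value <- final_value %||% y[length(y)]
  tol <- band * abs(final_value)
  if (abs(final_value) < 1e-9) {
    step <- abs(final_value - y[1])
    warn_pf("settling final value is ~0; falling back to a band of ",
            band, " * |step|")
    tol <- band * step
  }
  inside <- abs(y - final_value) <= tol
  if (!inside[length(inside)]) {
    warn_pf("response never permanently enters the settling band")
    return(NA_real_)
  }
  last_out <- max(c(0L, which(!inside)))
  if (last_out == 0L) return(0)  # inside the band from onset onwards
  t[last_out + 1L] - t_onset
}

#' Compare prediction errors between consecutive fitting stages
#'
#' Paired two-sided Wilcoxon signed-rank tests between consecutive
#' stages' per-subject PE values, per variable, flagged at 0.05 and 0.01
#' (a rank test is used because prediction errors of physiological data
#' are typically non-normal). Also reports the relative overall-PE change
#' between the first and last stage.
#'
#' @param pe_by_stage Named list (stage order preserved) of per-subject PE
#'   matrices or vectors: either `list(stage = c(subject = pe))` or
#'   per-variable data frames (subjects x variables).
#' @return List: `tests` (data frame: pair, variable, p, sig05, sig01),
#'   `overall_change_pct` (100 * (PE_first - PE_last) / PE_first, using
#'   the mean of per-subject PEs as the stage summary).
#' @export
compare_stages <- function(pe_by_stage) {
  stages <- names(pe_by_stage)
  stopifnot(length(stages) >= 2)
  as_mat <- function(x) {
    if (is.null(dim(x))) matrix(x, ncol = 1,
                                dimnames = list(names(x), "overall"))
    else as.matrix(x)
  }
  mats <- lapply(pe_by_stage, as_mat)
  tests <- list()
  for (i in seq_len(length(stages) - 1L)) {
    a <- mats[[i]]
    b <- mats[[i + 1L]]
    common <- intersect(rownames(a), rownames(b))
    if (length(common) < 5L) {
      warn_pf("fewer than 5 subjects; stage comparison ", stages[i],
              " vs ", stages[i + 1L], " skipped")
      next
    }
    for (v in colnames(a)) {
      d <- a[common, v] - b[common, v]
      p <- if (all(d == 0)) 1 else
        suppressWarnings(stats::wilcox.test(a[common, v], b[common, v],
                                            paired = TRUE)$p.value)
      tests[[length(tests) + 1L]] <- data.frame(
        pair = paste(stages[i], "vs", stages[i + 1L]),
        variable = v, p = p, sig05 = p < 0.05, sig01 = p < 0.01,
        stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(pair = character(0), variable = character(0),
               p = numeric(0), sig05 = logical(0), sig01 = logical(0))
  first <- mean(mats[[1L]])
  last <- mean(mats[[length(mats)]])
  list(tests = tests,
       overall_change_pct = 100 * (first - last) / first)
}

#' Validate fitted parameter vectors against a dataset
#'
#' Runs the steady-state validation (PE per variable, per subsystem and
#' overall, per stage) on the validation protocol and the transient
#' validation (percent change from rest and settling times for the first
#' load step) for each supplied parameter vector.
#'
#' @param model A `pf_model`.
#' @param params_by_stage Named list of full parameter vectors, in stage
#'   order (e.g. nominal, base, specific, stimulus).
#' @param dataset A `pf_dataset` at the validation protocol, already
#'   truncated at AT if desired.
#' @param transient_step Optional two-level protocol for the transient
#'   run (default: first two validation levels).
#' @param sample_dt Transient sampling interval (seconds).
#' @return A `pf_validation`: `pe` (per stage), `per_subject`,
#'   `comparison`, `settling` (stage x variable), `percent_change`.
#' @export
validate_model <- function(model, params_by_stage, dataset,
                           transient_step = NULL, sample_dt = 1) {
  proto <- dataset$protocol
  vars <- dataset$variables
  if (is.null(transient_step)) {
    transient_step <- stimulus_protocol(proto$vo2[1:2], proto$vco2[1:2],
                                        proto$step_duration,
                                        proto$settle_window)
  }
  var_subs <- stats::setNames(model$variables$subsystem,
                              model$variables$name)
  pe <- list()
  per_subject <- list()
  subsystem_tab <- list()
  settling <- list()
  pchange <- list()
  for (stage in names(params_by_stage)) {
    p <- full_params(model, params_by_stage[[stage]])
    sim <- simulate_steady_state(model, p, proto)
    pe[[stage]] <- prediction_error(dataset, sim, vars)
    per_subject[[stage]] <- per_subject_pe(dataset, sim, vars)
    subsystem_tab[[stage]] <- vapply(
      unique(var_subs[vars]), function(g) {
        vs <- vars[var_subs[vars] == g]
        x <- per_subject_pe(dataset, sim, vs)
        c(mean = mean(x), sd = stats::sd(x))
      }, numeric(2))
    tr <- simulate_transient(model, p, transient_step,
                             sample_dt = sample_dt)
    onset <- transient_step$step_duration
    st <- vapply(vars, function(v) {
      y <- tr$values[v, ]
      fin <- mean(y[tr$time >= max(tr$time) - proto$settle_window])
      suppressWarnings(settling_time(y, tr$time, t_onset = onset,
                                     final_value = fin))
    }, numeric(1))
    settling[[stage]] <- st
    base_idx <- which(tr$time <= onset)
    pchange[[stage]] <- lapply(stats::setNames(vars, vars), function(v) {
      percent_change_from_rest(tr$values[v, ],
                               tr$values[v, max(base_idx)])
    })
  }
  comparison <- if (length(per_subject) >= 2) {
    compare_stages(per_subject)
  } else NULL
  structure(list(pe = pe, per_subject = per_subject,
                 per_subsystem = subsystem_tab,
                 comparison = comparison,
                 settling = do.call(rbind, settling),
                 percent_change = pchange),
            class = "pf_validation")
}

#' @export
print.pf_validation <- function(x, ...) {
  cat("Validation report\n")
  for (s in names(x$pe)) {
    cat(sprintf("  %-9s PE = %.2f%%\n", s, x$pe[[s]]$pe))
  }
  if (!is.null(x$comparison)) {
    cat(sprintf("  overall PE change first->last: %.1f%%\n",
                x$comparison$overall_change_pct))
  }
  invisible(x)
}

#' Serialize a validation report
#'
#' JSON plus tab-separated per-variable PE and settling-time tables.
#'
#' @param report A `pf_validation`.
#' @param dir Output directory.
#' @export
write_validation <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pv <- do.call(rbind, lapply(names(report$pe), function(s) {
    data.frame(stage = s,
               variable = names(report$pe[[s]]$per_variable),
               pe_pct = as.numeric(report$pe[[s]]$per_variable))
  }))
  utils::write.table(pv, file.path(dir, "pe_per_variable.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(report$settling)) {
    st <- data.frame(stage = rownames(report$settling), report$settling)
    utils::write.table(st, file.path(dir, "settling_times.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(pe = lapply(report$pe, function(z)
      list(overall = z$pe, per_variable = as.list(z$per_variable))),
      comparison = if (!is.null(report$comparison))
        list(overall_change_pct = report$comparison$overall_change_pct,
             tests = report$comparison$tests),
      settling = report$settling),
    file.path(dir, "validation.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
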