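# Staged fitting: cost function, evaluation ranges, CMA-ES configuration
# and the three sequential optimization stages (base -> specific ->
# stimulus-related) with freeze semantics.

#' Relative root-mean-square cost function
#'
#' `CF = (1/I) * sum_i sqrt((1/K) * sum_k ((yexp - ysim) / yexp)^2)`:
#' per-variable RMS of the relative errors over stimulus levels, averaged
#' over variables. Zero iff the prediction matches every reference value.
#'
#' @param yexp Experimental reference matrix (variables x levels), all
#'   entries nonzero.
#' @param ysim Simulated matrix aligned with `yexp` (a `pf_steady` is also
#'   accepted).
#' @return Non-negative scalar cost.
#' @export
cost_function <- function(yexp, ysim) {
  if (inherits(ysim, "pf_steady")) {
    ysim <- ysim$values[rownames(yexp), , drop = FALSE]
  }
  stopifnot(identical(dim(yexp), dim(ysim)))
  zero <- which(yexp == 0, arr.ind = TRUE)
  if (nrow(zero)) {
    stop_pf("zero experimental value at (",
            rownames(yexp)[zero[1, 1]], ", level ", zero[1, 2], ")")
  }
  rel <- (yexp - ysim) / yexp
  mean(sqrt(rowMeans(rel^2)))
}

#' CMA-ES configuration for one fitting stage
#'
#' Defaults follow the standard parameterization for this class of
#' problem: function-evaluation termination tolerance 1e-12, tolerance on
#' x 1e-3, iteration cap 100 N^2, 500 function evaluations per restart, 10
#' restarts, population size `4 + floor(3 ln N)` and initial coordinate
#' step 0.2 (UB - LB).
#'
#' @param n_free Number of free parameters N of the stage.
#' @param seed Integer seed.
#' @param tol_fun,tol_x,max_iter,max_fun_eval,max_restart,pop_size,sigma0
#'   Overrides of the defaults.
#' @return An `pf_optconfig` list.
#' @export
optimizer_config <- function(n_free, seed, tol_fun = 1e-12, tol_x = 1e-3,
                             max_iter = NULL, max_fun_eval = 500,
                             max_restart = 10, pop_size = NULL,
                             sigma0 = 0.2) {
  stopifnot(n_free >= 1, tol_fun > 0, tol_x > 0, max_fun_eval > 0)
  pop_size <- pop_size %||% max(4L, 4L + as.integer(floor(3 * log(n_free))))
  max_iter <- max_iter %||% (100 * n_free^2)
  structure(list(n_free = n_free, seed = seed, tol_fun = tol_fun,
                 tol_x = tol_x, max_iter = max_iter,
                 max_fun_eval = max_fun_eval, max_restart = max_restart,
                 pop_size = pop_size, sigma0 = sigma0),
            class = "pf_optconfig")
}

#' Build evaluation ranges for a set of free parameters
#'
#' Every parameter gets the general range of +/-30% of its nominal value
#' unless the registry declares other default fractions or an explicit
#' override narrows/widens it. Absolute bounds are `nominal * (1 +
#' fraction)` (orientation is fixed so that lower < upper also for
#' negative nominals).
#'
#' @param free Free parameter names.
#' @param registry A `pf_registry`.
#' @param overrides Optional named list `name = c(lower, upper)` of signed
#'   fractions (literature-style overrides, e.g. `c(-0.70, 0.30)`).
#' @return A `pf_bounds` data frame: name, lower/upper fractions,
#'   absolute `lo`/`hi`, `source`.
#' @export
build_bounds <- function(free, registry, overrides = NULL) {
  idx <- match(free, registry$name)
  if (anyNA(idx)) {
    stop_pf("unknown parameter(s): ",
            paste(free[is.na(idx)], collapse = ", "))
  }
  lower <- registry$lower[idx]
  upper <- registry$upper[idx]
  source <- rep("default_pm30", length(free))
  source[lower != -0.30 | upper != 0.30] <- "registry_default"
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      if (!nm %in% free) next
      ov <- overrides[[nm]]
      if (ov[1] >= ov[2]) {
        stop_pf("override for '", nm, "': lower >= upper")
      }
      i <- match(nm, free)
      lower[i] <- ov[1]
      upper[i] <- ov[2]
      source[i] <- "literature_override"
    }
  }
  nominal <- registry$nominal[idx]
  a <- nominal * (1 + lower)
  b <- nominal * (1 + upper)
  out <- data.frame(name = free, lower = lower, upper = upper,
                    lo = pmin(a, b), hi = pmax(a, b), source = source,
                    stringsAsFactors = FALSE)
  inside <- nominal >= out$lo & nominal <= out$hi
  if (!all(inside)) {
    stop_pf("nominal outside its own bounds for: ",
            paste(free[!inside], collapse = ", "))
  }
  class(out) <- c("pf_bounds", "data.frame")
  out
}

#' Fit one stage with CMA-ES
#'
#' Minimizes the [cost_function()] over the free parameters inside their
#' bounds while every other parameter stays at its frozen (or nominal)
#' value. Optimization runs in coordinates scaled to `[0, 1]` over the
#' bound range; candidates outside the box are repaired, so every
#' reported value is feasible. The best-ever candidate is reported, never
#' the last.
#'
#' @param model A `pf_model`.
#' @param dataset A `pf_dataset`; its cohort means at the fitting protocol
#'   levels are the reference.
#' @param free Free parameter names (nonempty, disjoint from frozen).
#' @param frozen_values Named vector of values fixed by earlier stages or
#'   standardization (may be empty).
#' @param bounds A [build_bounds()] result covering `free`.
#' @param config An [optimizer_config()].
#' @param protocol Fitting protocol (default: the dataset's).
#' @return A `pf_fit`: `stage` (filled by the caller), `fitted`,
#'   `cf_initial`, `cf_final`, `evaluations`, `seed`, `at_bound`.
#' @export
fit_stage <- function(model, dataset, free, frozen_values = NULL,
                      bounds, config, protocol = NULL) {
  stopifnot(length(free) >= 1)
  if (length(intersect(free, names(frozen_values)))) {
    stop_pf("free parameters overlap the frozen set")
  }
  protocol <- protocol %||% dataset$protocol
  vars <- intersect(model_variables(model, fitting = TRUE),
                    dataset$variables)
  yexp <- cohort_means(dataset, vars)
  b <- bounds[match(free, bounds$name), , drop = FALSE]
  if (anyNA(b$lo)) stop_pf("bounds missing for some free parameters")
  lo <- b$lo
  hi <- b$hi
  base_params <- full_params(model, frozen_values)
  n_fail <- 0L
  n_eval <- 0L
  obj <- function(x) {
    u <- lo + x * (hi - lo)
    p <- base_params
    p[free] <- u
    n_eval <<- n_eval + 1L
    out <- tryCatch({
      sim <- simulate_steady_state(model, p, protocol)
      cost_function(yexp, sim$values[vars, , drop = FALSE])
    }, error = function(e) NA_real_)
    if (is.na(out)) {
      n_fail <<- n_fail + 1L
      return(Inf)
    }
    out
  }
  x0 <- (base_params[free] - lo) / (hi - lo)
  x0 <- pmin(pmax(x0, 0), 1)
  cf_initial <- obj(x0)
  res <- cma_es_min(obj, x0, lower = 0, upper = 1, sigma0 = config$sigma0,
                    pop_size = config$pop_size, tol_fun = config$tol_fun,
                    tol_x = config$tol_x, max_iter = config$max_iter,
                    max_fun_eval = config$max_fun_eval,
                    max_restart = config$max_restart, seed = config$seed)
  if (n_fail >= n_eval) {
    stop_pf("every candidate simulation failed during the stage")
  }
  u_best <- lo + res$par * (hi - lo)
  names(u_best) <- free
  at_bound <- free[res$par < 1e-6 | res$par > 1 - 1e-6]
  structure(list(stage = NA_character_,
                 fitted = u_best,
                 cf_initial = cf_initial,
                 cf_final = min(res$value, cf_initial),
                 evaluations = res$counteval,
                 restarts = res$restarts,
                 trace = res$trace,
                 seed = config$seed,
                 at_bound = at_bound,
                 bounds = b),
            class = "pf_fit")
}

#' Run the three sequential fitting stages
#'
#' Stages execute in order base -> specific -> stimulus-related. Each
#' stage freezes the standardized values and everything fitted by earlier
#' stages, and optimizes only its own set. Stages with an empty set are
#' skipped. The final parameter vector merges standardized, base,
#' specific and stimulus values over the nominals.
#'
#' @param model A `pf_model`.
#' @param dataset A `pf_dataset`.
#' @param plan A `pf_plan` from [build_selection_plan()].
#' @param bounds A [build_bounds()] result covering all fitted sets (built
#'   automatically when `NULL`).
#' @param config Optional base [optimizer_config()]; per-stage configs are
#'   derived from it with the stage's N and a stage-offset seed.
#' @param seed Master seed used when `config` is `NULL`.
#' @param overrides Bound overrides passed to [build_bounds()] when bounds
#'   are built here.
#' @param protocol Fitting protocol (default: the dataset's).
#' @return A `pf_staged_fit`: `stages` (list of `pf_fit`), `final_params`,
#'   `cf_path` (named CF after each stage, starting at the nominal CF).
#' @export
run_three_stage_fit <- function(model, dataset, plan, bounds = NULL,
                                config = NULL, seed = 1L, overrides = NULL,
                                protocol = NULL) {
  protocol <- protocol %||% dataset$protocol
  sets <- list(base = plan$base_set,
               specific = unname(plan$specific_set),
               stimulus = plan$stimulus_set$parameter)
  sets <- Filter(length, sets)
  all_free <- unlist(sets)
  if (is.null(bounds)) {
    bounds <- build_bounds(all_free, model$registry, overrides)
  }
  frozen <- plan$standardized
  vars <- intersect(model_variables(model, fitting = TRUE),
                    dataset$variables)
  yexp <- cohort_means(dataset, vars)
  cf_at <- function(values) {
    p <- full_params(model, values)
    cost_function(yexp,
                  simulate_steady_state(model, p, protocol)$values[vars, ,
                                                                   drop = FALSE])
  }
  cf_path <- c(nominal = cf_at(frozen))
  stages <- list()
  for (stage in names(sets)) {
    free <- sets[[stage]]
    cfg <- if (is.null(config)) {
      optimizer_config(length(free),
                       seed = seed + match(stage, c("base", "specific",
                                                    "stimulus")))
    } else {
      optimizer_config(length(free), seed = config$seed +
                         match(stage, c("base", "specific", "stimulus")),
                       tol_fun = config$tol_fun, tol_x = config$tol_x,
                       max_fun_eval = config$max_fun_eval,
                       max_restart = config$max_restart,
                       sigma0 = config$sigma0)
    }
    fit <- fit_stage(model, dataset, free, frozen, bounds, cfg, protocol)
    fit$stage <- stage
    stages[[stage]] <- fit
    frozen <- c(frozen, fit$fitted)
    cf_path[stage] <- fit$cf_final
  }
  final_params <- full_params(model, frozen)
  structure(list(stages = stages, final_params = final_params,
                 fitted_values = frozen, cf_path = cf_path,
                 bounds = bounds, seed = seed),
            class = "pf_staged_fit")
}

#' @export
print.pf_staged_fit <- function(x, ...) {
  cat("Three-stage fit\n")
  print(signif(x$cf_path, 4))
  for (s in names(x$stages)) {
    f <- x$stages[[s]]
    cat(sprintf("  %-9s %d params, CF %.3g -> %.3g (%d evals)\n", s,
                length(f$fitted), f$cf_initial, f$cf_final, f$evaluations))
  }
  invisible(x)
}

#' Serialize staged-fit results to JSON and a comparison table
#'
#' @param fit A `pf_staged_fit`.
#' @param path JSON output path; a `<path>.tsv` nominal-vs-fitted table is
#'   written alongside.
#' @param registry Registry supplying nominal values for the table.
#' @export
write_fit <- function(fit, path, registry) {
  jsonlite::write_json(
    list(cf_path = as.list(fit$cf_path),
         stages = lapply(fit$stages, function(f) {
           list(stage = f$stage, fitted = as.list(f$fitted),
                cf_initial = f$cf_initial, cf_final = f$cf_final,
                evaluations = f$evaluations, seed = f$seed,
                at_bound = f$at_bound)
         }),
         seed = fit$seed),
    path, auto_unbox = TRUE, digits = NA)
  rows <- do.call(rbind, lapply(fit$stages, function(f) {
    data.frame(stage = f$stage, parameter = names(f$fitted),
               nominal = registry$nominal[match(names(f$fitted),
                                                registry$name)],
               fitted = as.numeric(f$fitted), stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
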