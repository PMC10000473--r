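# Pipeline driver: run configuration, per-step runners and the end-to-end
# pipeline (synth -> screen -> select -> fit -> validate). Every step
# consumes only serialized artifacts of earlier steps, so runs are
# restartable; the resolved configuration (all defaults echoed) is written
# next to the results.

pf_config_defaults <- function() {
  list(
    model = "minicr",
    n_subjects = 20,
    noise = list(inter_subject_cv = 0.10, measurement_cv = 0.05),
    fit_protocol = list(vo2 = c(0.35, 0.76, 1.17),
                        vco2 = c(0.30, 0.65, 1.00),
                        step_duration = 3000, settle_window = 60),
    validation_protocol = list(vo2 = 1.17 * seq(0.3, 1.0, length.out = 8),
                               vco2 = seq(0.3, 1.0, length.out = 8),
                               step_duration = 3000, settle_window = 60),
    grid_h = c(-0.05, -0.025, 0.025, 0.05),
    eps = 1e-6,
    bound_overrides = NULL,
    optimizer = list(tol_fun = 1e-12, tol_x = 1e-3, max_fun_eval = 500,
                     max_restart = 10, sigma0 = 0.2)
  )
}

#' Read and resolve a run configuration
#'
#' Loads a YAML run configuration, validates it against the known fields
#' and fills every unspecified field with its default (no silent
#' defaults: the resolved configuration is returned in full and written
#' next to results by [run_pipeline()]).
#'
#' @param path YAML file path, or `NULL` for the all-defaults
#'   configuration.
#' @return A `pf_config` list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- pf_config_defaults()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop_pf("unknown configuration field(s): ",
              paste(unknown, collapse = ", "))
    }
    for (nm in names(user)) {
      cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
        utils::modifyList(cfg[[nm]], user[[nm]])
      } else user[[nm]]
    }
  }
  if (cfg$model != "minicr") {
    stop_pf("unknown model '", cfg$model, "'")
  }
  structure(cfg, class = "pf_config")
}

pf_model_from_config <- function(config) {
  minicr_model()
}

pf_protocol_from_config <- function(p) {
  stimulus_protocol(p$vo2, p$vco2, p$step_duration, p$settle_window)
}

#' Run the full pipeline
#'
#' Generates a synthetic cohort, screens and selects parameters, runs the
#' three fitting stages and validates nominal vs fitted predictions,
#' writing every artifact (dataset, screening, plan, fits, validation,
#' resolved configuration and seeds) under `out_dir`. One master seed is
#' expanded into named sub-seeds (cohort, optimizer stages) recorded in
#' the outputs.
#'
#' @param config A `pf_config` (default: all defaults).
#' @param seed Master integer seed.
#' @param out_dir Output directory.
#' @return Invisibly, a list with the in-memory artifacts (`dataset`,
#'   `screening`, `plan`, `fit`, `validation`).
#' @export
run_pipeline <- function(config = read_run_config(), seed, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- pf_model_from_config(config)
  seeds <- list(cohort = seed, optimizer = seed + 1000)
  t0 <- Sys.time()
  log_step <- function(step) {
    message(sprintf("[physiofit] %-10s %+6.1f s", step,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }

  fit_proto <- pf_protocol_from_config(config$fit_protocol)
  val_proto <- pf_protocol_from_config(config$validation_protocol)
  noise <- noise_model(config$noise$inter_subject_cv,
                       config$noise$measurement_cv)

  dataset <- generate_cohort(model, NULL, fit_proto, config$n_subjects,
                             noise, seed = seeds$cohort)
  write_dataset(dataset, file.path(out_dir, "dataset_fit.tsv"))
  log_step("synth")

  screening <- screen_parameters(model, dataset,
                                 grid = perturbation_grid(config$grid_h),
                                 eps = config$eps)
  write_screening(screening, file.path(out_dir, "screening"))
  log_step("screen")

  plan <- build_selection_plan(model, dataset, screening, eps = config$eps)
  write_plan(plan, file.path(out_dir, "plan.json"))
  log_step("select")

  opt <- config$optimizer
  base_cfg <- optimizer_config(1, seed = seeds$optimizer,
                               tol_fun = opt$tol_fun, tol_x = opt$tol_x,
                               max_fun_eval = opt$max_fun_eval,
                               max_restart = opt$max_restart,
                               sigma0 = opt$sigma0)
  fit <- run_three_stage_fit(model, dataset, plan, config = base_cfg,
                             seed = seeds$optimizer,
                             overrides = config$bound_overrides)
  write_fit(fit, file.path(out_dir, "fit.json"), model$registry)
  log_step("fit")

  val_data <- generate_cohort(model, NULL, val_proto, config$n_subjects,
                              noise, seed = seeds$cohort)
  val_data <- truncate_at_AT(val_data)
  params_by_stage <- list(nominal = NULL)
  acc <- plan$standardized
  for (s in names(fit$stages)) {
    acc <- c(acc, fit$stages[[s]]$fitted)
    params_by_stage[[s]] <- acc
  }
  validation <- validate_model(model, params_by_stage, val_data,
                               sample_dt = 5)
  write_validation(validation, file.path(out_dir, "validation"))
  log_step("validate")

  jsonlite::write_json(c(unclass(config), list(seeds = seeds)),
                       file.path(out_dir, "config_resolved.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(dataset = dataset, screening = screening, plan = plan,
                 fit = fit, validation = validation, seeds = seeds))
}

#' Reference parameter counts of the full-scale cardiorespiratory model
#'
#' Role distribution and per-stage selection counts published for the
#' full-scale (316-parameter) cardiorespiratory exercise model that the
#' bundled demo model miniaturizes. Shipped as plain-text tables under
#' `extdata` and used by the reduction-percentage reporting.
#'
#' @return List with `roles` (data frame role/count), `stages` (data
#'   frame stage/n), and `total` (sum of role counts).
#' @export
reference_counts <- function() {
  roles <- utils::read.csv(system.file("extdata", "cr316_roles.csv",
                                       package = "physiofit"))
  stages <- utils::read.csv(system.file("extdata", "cr316_stage_counts.csv",
                                        package = "physiofit"))
  list(roles = roles, stages = stages, total = sum(roles$count))
}

#' Reduction report for the selection stages
#'
#' Applies [reduction_percent()] to a set of stage counts against a
#' registry total, as used for reporting how much each selection approach
#' shrinks the fitting problem.
#'
#' @param counts Reference counts as returned by [reference_counts()], or
#'   a compatible list.
#' @return Data frame: stage, n, reduction_pct.
#' @export
reduction_report <- function(counts = reference_counts()) {
  st <- counts$stages
  data.frame(stage = st$stage, n = st$n,
             reduction_pct = reduction_percent(st$n, counts$total))
}
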