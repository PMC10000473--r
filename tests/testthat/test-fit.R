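# Cost function, bounds, CMA-ES and the staged fit.

test_that("cost function reproduces hand-computed relative RMS values", {
  y1 <- matrix(10, 1, 1, dimnames = list("y", NULL))
  expect_equal(cost_function(y1, matrix(10, 1, 1)), 0)
  # one variable, one level, exp 10 sim 11 -> 0.1
  expect_equal(cost_function(y1, matrix(11, 1, 1)), 0.1)
  # two variables with constant relative errors 0.1 and 0.3 -> 0.2
  yexp <- matrix(c(10, 10, 10, 10), 2, 2,
                 dimnames = list(c("a", "b"), NULL))
  ysim <- rbind(c(11, 11), c(13, 13))
  expect_equal(cost_function(yexp, ysim), 0.2)
  # zero experimental value is rejected by name
  yz <- matrix(c(0, 1), 1, 2, dimnames = list("y", NULL))
  expect_error(cost_function(yz, yz), "y, level 1")
})

test_that("bounds default to +/-30% and honor literature overrides", {
  reg <- minicr_model()$registry
  b <- build_bounds(c("Gc", "Rtot"), reg)
  expect_equal(b$lower, c(-0.3, -0.3))
  expect_equal(b$lo, c(2.0, 17.6) * 0.7)
  expect_equal(b$hi, c(2.0, 17.6) * 1.3)
  # override applied verbatim (elastance-style wide lower bound)
  b2 <- build_bounds("Gc", reg, overrides = list(Gc = c(-0.70, 0.30)))
  expect_equal(b2$lower, -0.70)
  expect_equal(b2$lo, 2.0 * 0.30)
  expect_equal(b2$source, "literature_override")
  expect_error(build_bounds("Gc", reg, overrides = list(Gc = c(0.3, -0.3))),
               "lower >= upper")
  # negative nominal keeps lo < hi with the nominal inside
  bn <- build_bounds("hr_sat", reg)
  expect_lt(bn$lo, bn$hi)
  expect_true(bn$lo < -0.08 && -0.08 < bn$hi)
})

test_that("optimizer configuration follows the standard parameterization", {
  cfg <- optimizer_config(8, seed = 1)
  expect_equal(cfg$pop_size, 4 + floor(3 * log(8)))
  expect_equal(cfg$max_iter, 100 * 64)
  expect_equal(cfg$tol_fun, 1e-12)
  expect_equal(cfg$max_fun_eval, 500)
  expect_equal(cfg$max_restart, 10)
})

test_that("CMA-ES minimizes a shifted sphere and respects the box", {
  sphere <- function(x) sum((x - c(0.3, 0.7))^2)
  res <- cma_es_min(sphere, c(0.5, 0.5), 0, 1, seed = 1,
                    max_fun_eval = 400, max_restart = 3)
  expect_lt(res$value, 1e-10)
  expect_equal(res$par, c(0.3, 0.7), tolerance = 1e-4)
  # optimum outside the box -> solution pinned at the bound, feasible
  outside <- function(x) sum((x - 1.5)^2)
  res2 <- cma_es_min(outside, 0.5, 0, 1, seed = 1, max_fun_eval = 300,
                     max_restart = 2)
  expect_true(all(res2$par >= 0 & res2$par <= 1))
  expect_equal(res2$par, 1, tolerance = 1e-6)
  # seeded determinism
  res3 <- cma_es_min(sphere, c(0.5, 0.5), 0, 1, seed = 1,
                     max_fun_eval = 400, max_restart = 3)
  expect_identical(res, res3)
})

test_that("fit_stage recovers the optimum of the identity model within tol_x", {
  m <- toy_identity_model()
  proto <- stimulus_protocol(1, 1, 100, 10)
  ustar <- 1.2
  ds <- matrix_dataset(matrix(ustar, 1, 1, dimnames = list("y", NULL)),
                       proto)
  bounds <- build_bounds("u", m$registry)
  cfg <- optimizer_config(1, seed = 3, max_fun_eval = 300, max_restart = 3)
  fit <- fit_stage(m, ds, "u", NULL, bounds, cfg)
  expect_equal(unname(fit$fitted["u"]), ustar, tolerance = 1e-3)
  expect_lte(fit$cf_final, fit$cf_initial)
})

test_that("a single perturbed gain is recovered on zero-noise MiniCR data", {
  fx <- minicr_fixture(n_subjects = 3, noise = noise_model(0, 0))
  m <- fx$model
  # truth = nominal; start the free gain from +20% via its frozen nominal
  bounds <- build_bounds("Gc", m$registry)
  cfg <- optimizer_config(1, seed = 5)
  # perturb the start by handing the optimizer a shifted base point
  reg2 <- m$registry
  truth_gc <- reg2$nominal[reg2$name == "Gc"]
  m2 <- m
  m2$registry$nominal[m2$registry$name == "Gc"] <-
    truth_gc * 1.2
  fit <- fit_stage(m2, fx$dataset, "Gc", NULL,
                   build_bounds("Gc", m2$registry), cfg)
  expect_lt(abs(fit$fitted[["Gc"]] / truth_gc - 1), 0.01)
  expect_lt(fit$cf_final, 1e-6)
  # seed-reproducible
  fit2 <- fit_stage(m2, fx$dataset, "Gc", NULL,
                    build_bounds("Gc", m2$registry), cfg)
  expect_identical(fit$fitted, fit2$fitted)
})

test_that("an optimum outside the bounds is reported at the bound", {
  m <- toy_identity_model()
  proto <- stimulus_protocol(1, 1, 100, 10)
  # y_exp chosen above the +30% bound of the nominal 1
  ds <- matrix_dataset(matrix(2.0, 1, 1, dimnames = list("y", NULL)),
                       proto)
  bounds <- build_bounds("u", m$registry)
  cfg <- optimizer_config(1, seed = 4, max_fun_eval = 200, max_restart = 2)
  fit <- fit_stage(m, ds, "u", NULL, bounds, cfg)
  expect_true("u" %in% fit$at_bound)
  expect_lte(fit$fitted[["u"]], bounds$hi + 1e-12)
})

test_that("a plan with empty specific and stimulus sets degenerates to a base fit", {
  fx <- minicr_fixture(n_subjects = 3, noise = noise_model(0, 0))
  plan <- structure(list(
    standardized = numeric(0),
    base_set = c("Gc", "Bc"),
    specific_set = setNames(character(0), character(0)),
    stimulus_set = data.frame(mechanism = character(0),
                              activity = character(0),
                              parameter = character(0))
  ), class = "pf_plan")
  cfg <- optimizer_config(1, seed = 2, max_fun_eval = 200, max_restart = 1)
  fit <- run_three_stage_fit(fx$model, fx$dataset, plan, config = cfg,
                             seed = 2)
  expect_equal(names(fit$stages), "base")
})

test_that("an already-optimal zero-noise cohort stays at the nominal values", {
  fx <- minicr_fixture(n_subjects = 3, noise = noise_model(0, 0))
  sc <- screen_parameters(fx$model, fx$dataset)
  plan <- quiet_plan(fx$model, fx$dataset, sc)
  cfg <- optimizer_config(1, seed = 6, max_fun_eval = 250, max_restart = 1)
  fit <- run_three_stage_fit(fx$model, fx$dataset, plan, config = cfg,
                             seed = 6)
  expect_lt(utils::tail(fit$cf_path, 1), 1e-6)
  nom <- nominal_params(fx$model$registry)
  free <- names(fit$fitted_values)
  free <- setdiff(free, names(plan$standardized))
  expect_lt(max(abs(fit$fitted_values[free] / nom[free] - 1)), 0.02)
})

test_that("monotone improvement and bound feasibility hold across seeds", {
  fx <- minicr_fixture(n_subjects = 3, noise = noise_model(0, 0.05),
                       seed = 9)
  bounds <- build_bounds(c("Gc", "Bc"), fx$model$registry)
  for (seed in 1:5) {
    cfg <- optimizer_config(2, seed = seed, max_fun_eval = 150,
                            max_restart = 1)
    fit <- fit_stage(fx$model, fx$dataset, c("Gc", "Bc"), NULL, bounds,
                     cfg)
    expect_lte(fit$cf_final, fit$cf_initial)
    expect_true(all(fit$fitted >= bounds$lo - 1e-12 &
                      fit$fitted <= bounds$hi + 1e-12))
  }
})
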