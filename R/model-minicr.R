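# MiniCR: a compact cardiorespiratory model of incremental aerobic
# exercise used for all examples and tests. It preserves the subsystem
# structure, observed-variable set and nonlinearity classes (controller
# saturation, exponential hypoxic chemoreflex, hyperbolic alveolar gas
# exchange) of full-scale cardiorespiratory exercise models at desk scale.
#
# Steady state at one stimulus level (VO2, VCO2 in L/min):
#   PIO2  = FiO2  * (Patm - p_h2o)        inspired O2 pressure, mmHg
#   PICO2 = FiCO2 * (Patm - p_h2o)
#   gas exchange (alveolar air equations, k_gas = 863 mmHg):
#     PACO2 = PICO2 + k_gas * VCO2 / (eff_gas * VA)
#     PAO2  = PIO2  - k_gas * VO2  / (eff_gas * VA)
#   ventilation controller (scalar fixed point in alveolar ventilation VA;
#   dv = VCO2 - VCO2_rest, with a quadratic acceleration of the metabolic
#   drive toward the anaerobic threshold):
#     VA = max(VA_min, Gc*(PACO2 - Bc) + Gp*exp(-PAO2/Kp)
#                      + Gm*dv*(1 + Gm2*dv))
#   breathing pattern:
#     BF = BF0 + kBF * VA;  VE = VA + BF * VD0;  VT = VE / BF
#     TI = 60 * DI / BF
#   cardiovascular:
#     dVO2 = VO2 - VO2_rest
#     CO = CO0 + kCO * dVO2 * (1 + kCO2 * dVO2)     (flattens near AT)
#     HR = HR0 + kHR * dVO2 * (1 + hr_sat * dVO2)   (flattens near AT)
#     PM = Pv0*(1 - g_mp*dVO2)                        (muscle pump)
#          + CO * Rtot * (1 - phi*dVO2*(1 + phi2*dVO2))  (vasodilation)
#     PP = (PP0 + kPP*(CO - CO0)) * (1 + g_rp*dVCO2)  (respiratory pump)
#     PS = PM + 2*PP/3;  PD = PM - PP/3
#
# Transients are first-order relaxations between successive steady states
# with one time constant per subsystem block (respiratory, cardiovascular,
# gas exchange).

MINICR_VARS <- data.frame(
  name = c("VE", "VT", "BF", "TI", "HR", "PS", "PD", "PM", "PAO2", "PACO2"),
  unit = c("L/min", "L", "1/min", "s", "bpm", "mmHg", "mmHg", "mmHg",
           "mmHg", "mmHg"),
  subsystem = c("respiratory_mechanics", "respiratory_mechanics",
                "respiratory_mechanics", "respiratory_mechanics",
                "cardiovascular_system", "cardiovascular_system",
                "cardiovascular_system", "cardiovascular_system",
                "gas_exchange", "gas_exchange"),
  stringsAsFactors = FALSE
)

minicr_registry <- function() {
  parameter_registry(
    # -- time constants (seconds) ---------------------------------------
    param_spec("tau_resp", 90, "time_constant", "respiratory_mechanics", "s"),
    param_spec("tau_cardio", 90, "time_constant", "cardiovascular_system", "s"),
    param_spec("tau_gas", 300, "time_constant", "gas_exchange", "s"),
    # -- conversion constants -------------------------------------------
    param_spec("k_gas", 863, "conversion", "gas_exchange", "mmHg"),
    param_spec("p_h2o", 47, "conversion", "gas_exchange", "mmHg"),
    # -- covariates (simulation conditions) -----------------------------
    param_spec("FiO2", 0.2093, "covariate", "gas_exchange", "fraction"),
    param_spec("FiCO2", 0.0004, "covariate", "gas_exchange", "fraction"),
    param_spec("Patm", 760, "covariate", "gas_exchange", "mmHg"),
    param_spec("VO2_rest", 0.35, "covariate", "gas_exchange", "L/min"),
    param_spec("VCO2_rest", 0.30, "covariate", "gas_exchange", "L/min"),
    # -- initial values (transient integrator states) -------------------
    param_spec("VE_init", 8.3, "initial_value", "respiratory_mechanics",
               "L/min"),
    param_spec("HR_init", 70, "initial_value", "cardiovascular_system",
               "bpm"),
    param_spec("PACO2_init", 40, "initial_value", "gas_exchange", "mmHg"),
    # -- gains and thresholds -------------------------------------------
    # ventilation controller
    param_spec("Gc", 2.0, "gain_threshold", "respiratory_controller",
               "L/min/mmHg", mechanism = "chemoreflex",
               activity = "central CO2 drive"),
    param_spec("Bc", 37.0, "gain_threshold", "respiratory_controller",
               "mmHg"),
    param_spec("Gp", 30, "gain_threshold", "respiratory_controller",
               "L/min", mechanism = "chemoreflex",
               activity = "peripheral O2 drive"),
    param_spec("Kp", 30, "gain_threshold", "respiratory_controller",
               "mmHg"),
    param_spec("Gm", 8, "gain_threshold", "respiratory_controller",
               "L/min per L/min", mechanism = "metabolic_drive",
               activity = "ventilatory drive"),
    # curvature of the metabolic ventilatory drive (ventilation
    # accelerates toward the anaerobic threshold)
    param_spec("Gm2", 0.25, "gain_threshold", "respiratory_controller",
               "1/(L/min)", mechanism = "metabolic_drive",
               activity = "ventilatory drive"),
    param_spec("VA_min", 1.0, "gain_threshold", "respiratory_controller",
               "L/min"),
    # breathing pattern
    param_spec("BF0", 8, "gain_threshold", "respiratory_mechanics", "1/min"),
    param_spec("kBF", 0.55, "gain_threshold", "respiratory_mechanics",
               "1/L"),
    param_spec("VD0", 0.15, "gain_threshold", "respiratory_mechanics", "L"),
    param_spec("DI", 0.4, "gain_threshold", "respiratory_mechanics",
               "fraction"),
    # gas exchange
    param_spec("eff_gas", 0.95, "gain_threshold", "gas_exchange",
               "fraction"),
    # cardiovascular system
    param_spec("CO0", 5, "gain_threshold", "cardiovascular_system",
               "L/min"),
    param_spec("Rtot", 17.6, "gain_threshold", "cardiovascular_system",
               "mmHg/(L/min)"),
    param_spec("Pv0", 5, "gain_threshold", "cardiovascular_system", "mmHg"),
    # PP0 is flagged excluded: baseline pulse pressure is treated as
    # clinically non-modifiable for healthy-subject simulation.
    param_spec("PP0", 40, "gain_threshold", "cardiovascular_system", "mmHg",
               excluded = TRUE),
    param_spec("kPP", 6, "gain_threshold", "cardiovascular_system",
               "mmHg/(L/min)"),
    # cardiovascular controller
    param_spec("HR0", 70, "gain_threshold", "cardiovascular_controller",
               "bpm"),
    param_spec("kHR", 40, "gain_threshold", "cardiovascular_controller",
               "bpm/(L/min)", mechanism = "central_command",
               activity = "heart rate"),
    # saturation of the heart-rate response at high exercise intensity
    param_spec("hr_sat", -0.08, "gain_threshold",
               "cardiovascular_controller", "1/(L/min)",
               mechanism = "central_command", activity = "heart rate",
               lower = -0.30, upper = 0.30),
    param_spec("kCO", 5, "gain_threshold", "cardiovascular_controller",
               "L/min per L/min", mechanism = "central_command",
               activity = "cardiac output"),
    # flattening of the cardiac-output response at high intensity
    param_spec("kCO2", -0.06, "gain_threshold",
               "cardiovascular_controller", "1/(L/min)",
               mechanism = "central_command",
               activity = "cardiac output"),
    param_spec("phi", 0.4, "gain_threshold", "cardiovascular_controller",
               "1/(L/min)", mechanism = "central_command",
               activity = "vasodilation"),
    # curvature of the exercise vasodilation response
    param_spec("phi2", -0.10, "gain_threshold",
               "cardiovascular_controller", "1/(L/min)",
               mechanism = "central_command", activity = "vasodilation"),
    # exercise pumps acting on venous return and pulse pressure
    param_spec("g_mp", 0.15, "gain_threshold", "cardiovascular_system",
               "1/(L/min)", mechanism = "muscle_pump",
               activity = "venous return"),
    param_spec("g_rp", 0.06, "gain_threshold", "cardiovascular_system",
               "1/(L/min)", mechanism = "respiratory_pump",
               activity = "pulse pressure")
  )
}

#' The MiniCR demo cardiorespiratory model
#'
#' A compact fixed-point cardiorespiratory model for incremental aerobic
#' exercise with first-order transients. Observed variables are minute
#' ventilation (VE), tidal volume (VT), breathing frequency (BF),
#' inspiratory time (TI), heart rate (HR), systolic / diastolic / mean
#' arterial pressure (PS, PD, PM) and alveolar gas pressures (PAO2, PACO2).
#' Subsystems: cardiovascular system and controller, respiratory mechanics,
#' respiratory controller and gas exchange. Default nominal values give a
#' plausible healthy adult at rest (HR about 70 bpm, PACO2 about 40 mmHg,
#' VE about 8.5 L/min).
#'
#' VT is declared a derived variable (VT = VE / BF) and is excluded from
#' screening and fitting, but included in validation.
#'
#' @return A `pf_model` object.
#' @export
minicr_model <- function() {
  structure(list(
    name = "MiniCR",
    registry = minicr_registry(),
    variables = MINICR_VARS,
    derived_variables = "VT",
    # controller <-> controlled system adjacency used by the specific
    # selection rule
    related = list(
      respiratory_mechanics = c("respiratory_controller"),
      respiratory_controller = c("respiratory_mechanics", "gas_exchange"),
      gas_exchange = c("respiratory_controller"),
      cardiovascular_system = c("cardiovascular_controller"),
      cardiovascular_controller = c("cardiovascular_system")
    )
  ), class = c("minicr_model", "pf_model"))
}

# Ventilatory drive as a function of alveolar ventilation va (> 0).
# Strictly decreasing in va for Gc, Gp > 0.
minicr_drive <- function(p, va, vo2, vco2) {
  pio2 <- p[["FiO2"]] * (p[["Patm"]] - p[["p_h2o"]])
  pico2 <- p[["FiCO2"]] * (p[["Patm"]] - p[["p_h2o"]])
  paco2 <- pico2 + p[["k_gas"]] * vco2 / (p[["eff_gas"]] * va)
  pao2 <- pio2 - p[["k_gas"]] * vo2 / (p[["eff_gas"]] * va)
  dv <- vco2 - p[["VCO2_rest"]]
  p[["Gc"]] * (paco2 - p[["Bc"]]) + p[["Gp"]] * exp(-pao2 / p[["Kp"]]) +
    p[["Gm"]] * dv * (1 + p[["Gm2"]] * dv)
}

# Solve VA = max(VA_min, drive(VA)) for one level. Bracketed bisection on
# [VA_min, upper] followed by a Newton polish; tolerance 1e-10, cap 200.
minicr_solve_va <- function(p, vo2, vco2, tol = 1e-10, max_iter = 200) {
  va_min <- p[["VA_min"]]
  g <- function(va) minicr_drive(p, va, vo2, vco2) - va
  g_lo <- g(va_min)
  if (!is.finite(g_lo)) {
    stop_pf("non-finite ventilatory drive at VA_min (level VCO2 = ", vco2, ")")
  }
  if (g_lo <= 0) {
    # controller saturates at its floor
    return(va_min)
  }
  hi <- max(100, va_min * 2)
  while (g(hi) > 0 && hi < 1e6) hi <- hi * 2
  if (g(hi) > 0) {
    stop_pf("ventilation fixed point: no sign change on [",
            signif(va_min, 4), ", ", signif(hi, 4), "] at level VCO2 = ",
            vco2, " (residual ", signif(g(hi), 4), ")")
  }
  lo <- va_min
  for (iter in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    gm <- g(mid)
    if (!is.finite(gm)) {
      stop_pf("non-finite drive during bisection at VA = ", signif(mid, 6))
    }
    if (gm > 0) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  va <- (lo + hi) / 2
  # Newton polish with numerical derivative
  for (k in 1:3) {
    h <- max(1e-7 * va, 1e-9)
    gp <- (g(va + h) - g(va - h)) / (2 * h)
    if (!is.finite(gp) || abs(gp) < 1e-12) break
    step <- g(va) / gp
    va_new <- va - step
    if (va_new <= va_min || !is.finite(va_new)) break
    va <- va_new
    if (abs(step) < tol / 10) break
  }
  va
}

# Steady-state outputs at one level; returns a named vector over
# MINICR_VARS$name.
minicr_steady_level <- function(p, vo2, vco2) {
  va <- minicr_solve_va(p, vo2, vco2)
  pio2 <- p[["FiO2"]] * (p[["Patm"]] - p[["p_h2o"]])
  pico2 <- p[["FiCO2"]] * (p[["Patm"]] - p[["p_h2o"]])
  paco2 <- pico2 + p[["k_gas"]] * vco2 / (p[["eff_gas"]] * va)
  pao2 <- pio2 - p[["k_gas"]] * vo2 / (p[["eff_gas"]] * va)
  bf <- p[["BF0"]] + p[["kBF"]] * va
  ve <- va + bf * p[["VD0"]]
  vt <- ve / bf
  ti <- 60 * p[["DI"]] / bf
  dvo2 <- vo2 - p[["VO2_rest"]]
  co <- p[["CO0"]] + p[["kCO"]] * dvo2 * (1 + p[["kCO2"]] * dvo2)
  hr <- p[["HR0"]] + p[["kHR"]] * dvo2 * (1 + p[["hr_sat"]] * dvo2)
  dvco2 <- vco2 - p[["VCO2_rest"]]
  pm <- p[["Pv0"]] * (1 - p[["g_mp"]] * dvo2) +
    co * p[["Rtot"]] * (1 - p[["phi"]] * dvo2 * (1 + p[["phi2"]] * dvo2))
  pp <- (p[["PP0"]] + p[["kPP"]] * (co - p[["CO0"]])) *
    (1 + p[["g_rp"]] * dvco2)
  ps <- pm + 2 * pp / 3
  pd <- pm - pp / 3
  out <- c(VE = ve, VT = vt, BF = bf, TI = ti, HR = hr, PS = ps, PD = pd,
           PM = pm, PAO2 = pao2, PACO2 = paco2)
  bad <- names(out)[!is.finite(out)]
  if (length(bad)) {
    stop_pf("non-finite steady state for variable(s): ",
            paste(bad, collapse = ", "))
  }
  out
}

#' @rdname simulate_steady_state
#' @export
simulate_steady_state.minicr_model <- function(model, params = NULL,
                                               protocol) {
  p <- full_params(model, params)
  k <- n_levels(protocol)
  vals <- vapply(seq_len(k), function(i) {
    minicr_steady_level(p, protocol$vo2[i], protocol$vco2[i])
  }, numeric(nrow(MINICR_VARS)))
  vals <- matrix(vals, nrow = nrow(MINICR_VARS),
                 dimnames = list(MINICR_VARS$name, NULL))
  new_pf_steady(vals, p, protocol)
}

# Time constant per variable, by subsystem block.
minicr_taus <- function(p) {
  tau <- c(respiratory_mechanics = p[["tau_resp"]],
           cardiovascular_system = p[["tau_cardio"]],
           gas_exchange = p[["tau_gas"]])
  stats::setNames(tau[MINICR_VARS$subsystem], MINICR_VARS$name)
}

#' @rdname simulate_transient
#' @export
simulate_transient.minicr_model <- function(model, params = NULL, protocol,
                                            sample_dt = 1,
                                            init = c("steady", "params")) {
  init <- match.arg(init)
  stopifnot(sample_dt > 0)
  p <- full_params(model, params)
  ss <- simulate_steady_state(model, p, protocol)$values
  tau <- minicr_taus(p)
  k <- n_levels(protocol)
  times <- seq(0, k * protocol$step_duration, by = sample_dt)
  y0 <- ss[, 1]
  if (init == "params") {
    y0[["VE"]] <- p[["VE_init"]]
    y0[["HR"]] <- p[["HR_init"]]
    y0[["PACO2"]] <- p[["PACO2_init"]]
  }
  out <- matrix(NA_real_, nrow = nrow(ss), ncol = length(times),
                dimnames = list(rownames(ss), NULL))
  state <- y0
  t_prev <- 0
  for (idx in seq_along(times)) {
    t <- times[idx]
    level <- min(k, floor(t / protocol$step_duration) + 1L)
    if (t > t_prev) {
      # exact exponential update across [t_prev, t] (level is constant on
      # the interval because sample_dt divides evenly into step boundaries
      # only approximately; split at a boundary if one was crossed)
      t0 <- t_prev
      while (t0 < t) {
        lev0 <- min(k, floor(t0 / protocol$step_duration + 1e-9) + 1L)
        t_break <- min(t, lev0 * protocol$step_duration)
        dt <- t_break - t0
        target <- ss[, lev0]
        state <- target + (state - target) * exp(-dt / tau)
        t0 <- t_break
      }
    }
    if (!all(is.finite(state))) {
      stop_pf("non-finite transient state at t = ", t, " s")
    }
    out[, idx] <- state
    t_prev <- t
  }
  structure(list(values = out, time = times, params = p,
                 protocol = protocol),
            class = "pf_transient")
}

#' Default three-level fitting protocol for MiniCR
#'
#' Rest, intermediate exercise and anaerobic threshold, as three
#' consecutive, equidistant, incremental steps (VCO2 0.30 / 0.65 / 1.00
#' L/min).
#'
#' @param step_duration,settle_window Passed to [stimulus_protocol()].
#' @return A `pf_protocol` with three levels.
#' @export
minicr_protocol3 <- function(step_duration = 3000, settle_window = 60) {
  stimulus_protocol(vo2 = c(0.35, 0.76, 1.17),
                    vco2 = c(0.30, 0.65, 1.00),
                    step_duration = step_duration,
                    settle_window = settle_window)
}

#' Default eight-step validation protocol for MiniCR
#'
#' Eight incremental, successive, equidistant VCO2 steps from 0.3 to 1.0
#' L/min (VO2 = 1.17 * VCO2, a fixed aerobic gas-exchange ratio).
#'
#' @param step_duration,settle_window Passed to [stimulus_protocol()].
#' @return A `pf_protocol` with eight levels.
#' @export
minicr_protocol8 <- function(step_duration = 3000, settle_window = 60) {
  vco2 <- seq(0.3, 1.0, length.out = 8)
  stimulus_protocol(vo2 = 1.17 * vco2, vco2 = vco2,
                    step_duration = step_duration,
                    settle_window = settle_window)
}
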