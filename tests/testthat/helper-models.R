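# Shared fixtures: tiny contract-conforming models and cohort builders.

# A linear toy model: one observed variable y = sum(a * u) evaluated at
# every protocol level (levels only rescale y by the level's VCO2 so that
# level structure exists). Used to check derivatives and identities
# against closed forms.
toy_linear_model <- function(a) {
  reg <- parameter_registry(lapply(seq_along(a), function(j) {
    param_spec(paste0("u", j), nominal = 1, role = "gain_threshold",
               subsystem = "toy")
  }))
  m <- structure(list(
    name = "toy_linear",
    a = a,
    registry = reg,
    variables = data.frame(name = "y", unit = "", subsystem = "toy",
                           stringsAsFactors = FALSE),
    derived_variables = character(0),
    related = list(toy = character(0))
  ), class = c("toy_linear_model", "pf_model"))
  m
}

simulate_steady_state.toy_linear_model <- function(model, params = NULL,
                                                   protocol) {
  p <- full_params(model, params)
  y <- vapply(protocol$vco2, function(s) sum(model$a * p) * s, numeric(1))
  physiofit:::new_pf_steady(matrix(y, nrow = 1, dimnames = list("y", NULL)),
                            p, protocol)
}
registerS3method("simulate_steady_state", "toy_linear_model",
                 simulate_steady_state.toy_linear_model,
                 envir = asNamespace("physiofit"))

# identity model: y = u at every level (single parameter, single level use)
toy_identity_model <- function() {
  reg <- parameter_registry(param_spec("u", nominal = 1,
                                       role = "gain_threshold",
                                       subsystem = "toy"))
  structure(list(name = "toy_identity", registry = reg,
                 variables = data.frame(name = "y", unit = "",
                                        subsystem = "toy",
                                        stringsAsFactors = FALSE),
                 derived_variables = character(0),
                 related = list(toy = character(0))),
            class = c("toy_identity_model", "pf_model"))
}
simulate_steady_state.toy_identity_model <- function(model, params = NULL,
                                                     protocol) {
  p <- full_params(model, params)
  y <- rep(p[["u"]], n_levels(protocol))
  physiofit:::new_pf_steady(matrix(y, nrow = 1, dimnames = list("y", NULL)),
                            p, protocol)
}
registerS3method("simulate_steady_state", "toy_identity_model",
                 simulate_steady_state.toy_identity_model,
                 envir = asNamespace("physiofit"))

# dataset wrapper around an explicit variables x levels matrix (one
# "subject" whose observations are the matrix itself)
matrix_dataset <- function(values, protocol, covariates = list()) {
  k <- ncol(values)
  obs <- data.frame(
    subject = "S001",
    level = rep(seq_len(k), each = nrow(values)),
    vco2 = rep(protocol$vco2, each = nrow(values)),
    variable = rep(rownames(values), k),
    value = as.vector(values),
    stringsAsFactors = FALSE
  )
  structure(list(observations = obs, covariates = covariates,
                 at = c(S001 = max(protocol$vco2)),
                 true_params = NULL, subject_params = NULL,
                 protocol = protocol, variables = rownames(values),
                 noise_meta = list(inter_subject_cv = 0,
                                   measurement_cv = 0, seed = NA)),
            class = "pf_dataset")
}

# standard MiniCR fixtures
minicr_fixture <- function(n_subjects = 6, noise = noise_model(0, 0),
                           seed = 1, protocol = minicr_protocol3(),
                           true_params = NULL) {
  m <- minicr_model()
  ds <- generate_cohort(m, true_params, protocol, n_subjects, noise,
                        seed = seed)
  list(model = m, dataset = ds, protocol = protocol)
}

# selection plans emit expected warnings about fully-claimed mechanism
# activities; suppress them where the plan itself is under test
quiet_plan <- function(...) suppressWarnings(build_selection_plan(...))

# brute-force fixed point of the MiniCR ventilation controller: finest
# sign change of drive(VA) - VA on a grid, refined by bisection
brute_force_va <- function(p, vo2, vco2, lo = NULL, hi = 100,
                           tol = 1e-10) {
  lo <- if (is.null(lo)) p[["VA_min"]] else lo
  g <- function(va) physiofit:::minicr_drive(p, va, vo2, vco2) - va
  if (g(lo) <= 0) return(lo)
  grid <- seq(lo, hi, length.out = 2000)
  gv <- vapply(grid, g, numeric(1))
  i <- which(gv <= 0)[1]
  a <- grid[i - 1]; b <- grid[i]
  while (b - a > tol) {
    mid <- (a + b) / 2
    if (g(mid) > 0) a <- mid else b <- mid
  }
  (a + b) / 2
}
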