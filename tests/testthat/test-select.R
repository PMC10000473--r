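# Role filtering, standardization and the three fitted-set selections.

# registry shaped like a full-scale cardiorespiratory model: given role
# counts, built programmatically
make_counted_registry <- function(n_cov = 12, n_conv = 1, n_gain = 239,
                                  n_init = 24, n_tau = 40,
                                  n_excluded = 1) {
  specs <- list()
  add <- function(n, role, prefix) {
    lapply(seq_len(n), function(i) {
      param_spec(paste0(prefix, i), nominal = 1, role = role,
                 subsystem = "s1",
                 excluded = (prefix == "g" && i <= n_excluded))
    })
  }
  parameter_registry(c(add(n_cov, "covariate", "c"),
                       add(n_conv, "conversion", "k"),
                       add(n_gain, "gain_threshold", "g"),
                       add(n_init, "initial_value", "i"),
                       add(n_tau, "time_constant", "t")))
}

test_that("role filter keeps only non-excluded gains and thresholds", {
  reg <- make_counted_registry()
  expect_equal(nrow(reg), 316)
  cand <- role_filter(reg)
  expect_equal(length(cand), 239 - 1)
  expect_true(all(startsWith(cand, "g")))
  # registry of only time constants -> empty candidate set
  reg_tau <- parameter_registry(param_spec("t1", 10, "time_constant", "s"))
  expect_equal(role_filter(reg_tau), character(0))
})

test_that("standardization pins covariates to dataset values and shrinks nothing else", {
  fx <- minicr_fixture(n_subjects = 2, noise = noise_model(0, 0))
  ds <- fx$dataset
  ds$covariates$FiO2 <- 0.2093
  ds$covariates$Patm <- 640
  std <- standardize(fx$model$registry, ds)
  expect_equal(unname(std$values["FiO2"]), 0.2093)
  expect_equal(unname(std$values["Patm"]), 640)
  expect_true(all(std$registry$fixed[std$registry$role == "covariate"]))
  # candidate count is untouched by standardization of covariates (they
  # were never candidates), and drops by exactly the number of
  # standardized gain-role parameters (none in MiniCR)
  expect_equal(length(role_filter(std$registry)),
               length(role_filter(fx$model$registry)))
  # missing covariate errors by name
  ds$covariates$Patm <- NULL
  expect_error(standardize(fx$model$registry, ds), "Patm")
})

test_that("subset criterion admits exactly the scores above the tolerance", {
  reg <- parameter_registry(
    param_spec("p1", 1, "gain_threshold", "A"),
    param_spec("p2", 1, "gain_threshold", "A"),
    param_spec("p3", 1, "gain_threshold", "A"))
  fake <- structure(list(
    candidates = c("p1", "p2", "p3"),
    subset = list(Z = c(p1 = 1, p2 = 1e-3, p3 = 1e-8)),
    agg = list(s_j = c(p1 = 0.5, p2 = 0.4, p3 = 0.3))
  ), class = "pf_screening")
  base <- select_base(fake, eps = 1e-6, reg)
  expect_setequal(as.character(base), c("p1", "p2"))
})

test_that("sensitivity walk covers subsystems without duplicating covered ones", {
  reg <- parameter_registry(
    param_spec("a1", 1, "gain_threshold", "A"),
    param_spec("a2", 1, "gain_threshold", "A"),
    param_spec("b1", 1, "gain_threshold", "B"),
    param_spec("c1", 1, "gain_threshold", "C"))
  # A already covered by the subset criterion -> no second A parameter
  fake <- structure(list(
    candidates = c("a1", "a2", "b1", "c1"),
    subset = list(Z = c(a1 = 1, a2 = 1e-9, b1 = 1e-9, c1 = 1e-9)),
    agg = list(s_j = c(a2 = 0.9, b1 = 0.5, c1 = 0.1))
  ), class = "pf_screening")
  base <- select_base(fake, eps = 1e-6, reg)
  expect_setequal(as.character(base), c("a1", "b1", "c1"))

  # subset admits none; walk an interleaved ranking and stop exactly when
  # the third subsystem is first covered (brute-force walk oracle)
  fake2 <- structure(list(
    candidates = c("a1", "a2", "b1", "c1"),
    subset = list(Z = c(a1 = 1e-9, a2 = 1e-9, b1 = 1e-9, c1 = 1e-9)),
    agg = list(s_j = c(a1 = 0.9, b1 = 0.8, a2 = 0.7, c1 = 0.6))
  ), class = "pf_screening")
  base2 <- select_base(fake2, eps = 1e-6, reg)
  walk <- c("a1", "b1", "a2", "c1")
  subs <- c(a1 = "A", b1 = "B", a2 = "A", c1 = "C")
  covered <- character(0); picked <- character(0)
  for (p in walk) {
    if (length(unique(covered)) == 3) break
    if (!(subs[[p]] %in% covered)) {
      picked <- c(picked, p); covered <- c(covered, subs[[p]])
    }
  }
  expect_setequal(as.character(base2), picked)  # a1, b1, c1
})

test_that("base selection errors when a subsystem has no candidates", {
  reg <- parameter_registry(
    param_spec("a1", 1, "gain_threshold", "A"),
    param_spec("b1", 1, "gain_threshold", "B", excluded = TRUE))
  fake <- structure(list(
    candidates = "a1",
    subset = list(Z = c(a1 = 1)),
    agg = list(s_j = c(a1 = 0.5))
  ), class = "pf_screening")
  expect_error(select_base(fake, eps = 1e-6, reg), "B")
})

test_that("specific selection prefers specificity over raw sensitivity", {
  # two variables in unrelated subsystems; u1 tops y1's ranking but is
  # equally sensitive for unrelated y2; u2 is slightly lower for y1 with
  # near-zero cross-talk -> u2 wins for y1
  reg <- parameter_registry(
    param_spec("u1", 1, "gain_threshold", "A"),
    param_spec("u2", 1, "gain_threshold", "A"),
    param_spec("u3", 1, "gain_threshold", "B"))
  model <- list(registry = reg,
                variables = data.frame(name = c("y1", "y2"),
                                       unit = "", subsystem = c("A", "B"),
                                       stringsAsFactors = FALSE),
                related = list(A = character(0), B = character(0)))
  s_ij <- rbind(y1 = c(u1 = 1.0, u2 = 0.9, u3 = 0.05),
                y2 = c(u1 = 1.0, u2 = 0.02, u3 = 0.6))
  fake <- structure(list(agg = list(s_ij = s_ij)), class = "pf_screening")
  got <- select_specific(fake, base_set = character(0), model)
  expect_equal(unname(got["y1"]), "u2")
  expect_equal(unname(got["y2"]), "u3")
})

test_that("base-set parameters are removed from specific rankings", {
  reg <- parameter_registry(
    param_spec("u1", 1, "gain_threshold", "A"),
    param_spec("u2", 1, "gain_threshold", "A"))
  model <- list(registry = reg,
                variables = data.frame(name = "y1", unit = "",
                                       subsystem = "A",
                                       stringsAsFactors = FALSE),
                related = list(A = character(0)))
  s_ij <- rbind(y1 = c(u1 = 1.0, u2 = 0.5))
  fake <- structure(list(agg = list(s_ij = s_ij)), class = "pf_screening")
  got <- select_specific(fake, base_set = "u1", model)
  expect_equal(unname(got["y1"]), "u2")
})

test_that("stimulus selection takes one free parameter per mechanism activity", {
  reg <- parameter_registry(
    param_spec("m1", 1, "gain_threshold", "A", mechanism = "mech1",
               activity = "act1"),
    param_spec("m2", 1, "gain_threshold", "A", mechanism = "mech2",
               activity = "act1"),
    param_spec("m2b", 1, "gain_threshold", "A", mechanism = "mech2",
               activity = "act1"),
    param_spec("m3", 1, "gain_threshold", "A", mechanism = "mech3",
               activity = "act1"))
  # mech1's only parameter already in the specific set -> warning, skipped
  expect_warning(
    st <- select_stimulus(reg, base_set = character(0),
                          specific_set = c(y = "m1"),
                          s_j = c(m2 = 0.2, m2b = 0.9, m3 = 0.1)),
    "mech1")
  expect_equal(nrow(st), 2)
  # the higher-s_j parameter wins within a mechanism activity
  expect_equal(st$parameter[st$mechanism == "mech2"], "m2b")
  expect_equal(st$parameter[st$mechanism == "mech3"], "m3")
})

test_that("a mechanism with several activities yields one parameter per activity", {
  reg <- parameter_registry(lapply(1:4, function(i) {
    param_spec(paste0("g", i), 1, "gain_threshold", "A",
               mechanism = "central", activity = paste0("act", i))
  }))
  st <- select_stimulus(reg, character(0), character(0))
  expect_equal(nrow(st), 4)
  expect_setequal(st$activity, paste0("act", 1:4))
})

test_that("the three fitted sets are pairwise disjoint and exclude forbidden parameters", {
  fx <- minicr_fixture(n_subjects = 5, noise = noise_model(0.05, 0.03),
                       seed = 2)
  sc <- screen_parameters(fx$model, fx$dataset)
  plan <- quiet_plan(fx$model, fx$dataset, sc)
  all_fitted <- c(plan$base_set, unname(plan$specific_set),
                  plan$stimulus_set$parameter)
  expect_equal(anyDuplicated(all_fitted), 0L)
  reg <- fx$model$registry
  expect_length(intersect(all_fitted,
                          reg$name[reg$excluded |
                                     reg$role == "covariate"]), 0)
  # determinism: identical screening input -> identical plan
  plan2 <- quiet_plan(fx$model, fx$dataset, sc)
  expect_identical(plan, plan2)
})

test_that("reduction percentages reproduce the published counts arithmetic", {
  counts <- reference_counts()
  expect_equal(counts$total, 316)
  rep <- reduction_report(counts)
  get <- function(st) rep$reduction_pct[rep$stage == st]
  expect_equal(get("remaining_after_standardization"), 31.6)
  expect_equal(get("specific"), 97.2)
  expect_equal(get("stimulus"), 95.3)
  # MiniCR reductions match hand counting
  fx <- minicr_fixture(n_subjects = 4, noise = noise_model(0.05, 0.03))
  sc <- screen_parameters(fx$model, fx$dataset)
  plan <- quiet_plan(fx$model, fx$dataset, sc)
  n_total <- nrow(fx$model$registry)
  expect_equal(reduction_percent(length(plan$base_set), n_total),
               round_half_away(100 * (1 - length(plan$base_set) / n_total), 1))
})

test_that("plans round-trip through JSON", {
  fx <- minicr_fixture(n_subjects = 4, noise = noise_model(0.05, 0.03))
  sc <- screen_parameters(fx$model, fx$dataset)
  plan <- quiet_plan(fx$model, fx$dataset, sc)
  path <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, path)
  back <- read_plan(path)
  expect_equal(back$base_set, plan$base_set)
  expect_equal(back$specific_set, plan$specific_set)
  expect_equal(back$stimulus_set$parameter, plan$stimulus_set$parameter)
})
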