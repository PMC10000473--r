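# Subset selection and sensitivity analysis.

test_that("residual Jacobian recovers the analytic derivative of a linear model", {
  # y = a * u, residual r = y_exp - a * u => dr/du = -a
  a <- 2.5
  m <- toy_linear_model(a)
  proto <- stimulus_protocol(1, 1, 100, 10)
  ds <- matrix_dataset(matrix(3, 1, 1, dimnames = list("y", NULL)), proto)
  jac <- residual_jacobian(m, ds, NULL, level = 1, h = 0,
                           candidates = "u1")
  expect_equal(jac[1, 1], -a, tolerance = 1e-6)
})

test_that("a parameter the output ignores gives an all-zero Jacobian column", {
  m <- toy_linear_model(c(2, 0))   # y independent of u2
  proto <- stimulus_protocol(1, 1, 100, 10)
  ds <- matrix_dataset(matrix(3, 1, 1, dimnames = list("y", NULL)), proto)
  jac <- residual_jacobian(m, ds, NULL, level = 1, h = 0,
                           candidates = c("u1", "u2"))
  expect_equal(unname(jac[1, "u2"]), 0)
})

test_that("forward-difference MiniCR Jacobian matches a central-difference oracle", {
  fx <- minicr_fixture(n_subjects = 3, noise = noise_model(0, 0.03))
  cand <- c("Gc", "Bc", "Rtot", "kHR")
  fd <- 1e-6
  jac <- residual_jacobian(fx$model, fx$dataset, NULL, level = 2, h = 0,
                           candidates = cand, fd_step = fd)
  # central-difference oracle, computed independently
  p0 <- full_params(fx$model)
  proto1 <- stimulus_protocol(fx$protocol$vo2[2], fx$protocol$vco2[2])
  vars <- rownames(jac)
  oracle <- sapply(cand, function(pj) {
    d <- fd * abs(p0[[pj]])
    pp <- p0; pp[[pj]] <- pp[[pj]] + d
    pm <- p0; pm[[pj]] <- pm[[pj]] - d
    yp <- simulate_steady_state(fx$model, pp, proto1)$values[vars, 1]
    ym <- simulate_steady_state(fx$model, pm, proto1)$values[vars, 1]
    -(yp - ym) / (2 * d)
  })
  scale <- max(abs(oracle))
  expect_true(max(abs(jac - oracle)) / scale < 10 * fd)
})

test_that("subset selection reproduces the hand-computed SVD/QR of simple matrices", {
  # diagonal Jacobian diag(1, 0.5): singular values {1, 0.5}, full rank,
  # ordering (u1, u2), assigned normalized values {1, 0.5}
  jac <- diag(c(1, 0.5))
  dimnames(jac) <- list(c("y1", "y2"), c("u1", "u2"))
  res <- subset_selection_rank(list(list(jac)), eps = 1e-6)
  expect_equal(res$rho[1, 1], 2L)
  expect_equal(res$orderings[[1]][[1]], c("u1", "u2"))
  expect_equal(unname(res$Z[c("u1", "u2")]), c(1, 0.5))

  # zero column: unidentifiable parameter ranked last, below eps
  jac3 <- cbind(jac, u3 = c(0, 0))
  res3 <- subset_selection_rank(list(list(jac3)), eps = 1e-6)
  expect_equal(names(res3$Z)[3], "u3")
  expect_lt(res3$Z[["u3"]], 1e-6)

  # perfectly collinear pair: numerical rank 1, exactly one of the pair
  # in the estimable partition
  jac_c <- matrix(c(1, 2, 1, 2), 2, 2,
                  dimnames = list(c("y1", "y2"), c("u1", "u2")))
  res_c <- subset_selection_rank(list(list(jac_c)), eps = 1e-6)
  expect_equal(res_c$rho[1, 1], 1L)
  est <- res_c$orderings[[1]][[1]][1]
  expect_true(est %in% c("u1", "u2"))
  expect_gt(res_c$Z[[est]], 1e-6)
  expect_lt(res_c$Z[[setdiff(c("u1", "u2"), est)]], 1e-6)
})

test_that("all-zero Jacobians are rejected", {
  jac <- matrix(0, 2, 2, dimnames = list(c("y1", "y2"), c("u1", "u2")))
  expect_error(subset_selection_rank(list(list(jac))), "identifiable")
})

test_that("pivoted QR top choice matches exhaustive search on random small Jacobians", {
  # oracle: the best single column is the one maximizing the smallest
  # singular value of the selected submatrix (its norm, for one column)
  for (s in 1:20) {
    set.seed(100 + s)
    nr <- sample(2:4, 1)
    nc <- sample(2:4, 1)
    jac <- matrix(rnorm(nr * nc), nr, nc,
                  dimnames = list(paste0("y", 1:nr), paste0("u", 1:nc)))
    res <- subset_selection_rank(list(list(jac)), eps = 1e-10)
    top <- res$orderings[[1]][[1]][1]
    norms <- sqrt(colSums(jac^2))
    expect_equal(top, names(which.max(norms)))
  }
})

test_that("numerical rank equals the parameter count for a full-rank linear map", {
  set.seed(5)
  a <- matrix(rnorm(9), 3, 3)  # generic => full rank
  jac <- a
  dimnames(jac) <- list(paste0("y", 1:3), paste0("u", 1:3))
  kappa_inv <- min(svd(a)$d) / max(svd(a)$d)
  res <- subset_selection_rank(list(list(jac)), eps = kappa_inv / 10)
  expect_equal(res$rho[1, 1], 3L)
})

test_that("relative sensitivity is exactly 1 for a linear parameter map", {
  m <- toy_linear_model(3)
  proto <- stimulus_protocol(c(0.5, 1), c(0.5, 1), 100, 10)
  s <- relative_sensitivity_tensor(m, NULL, proto,
                                   candidates = "u1", variables = "y")
  expect_equal(as.vector(s), rep(1, length(s)), tolerance = 1e-12)
})

test_that("relative sensitivity is 0 for an ignored parameter and 2.05 for y = u^2", {
  m <- toy_linear_model(c(3, 0))
  proto <- stimulus_protocol(1, 1, 100, 10)
  s <- relative_sensitivity_tensor(m, NULL, proto,
                                   candidates = c("u1", "u2"),
                                   variables = "y")
  expect_equal(as.vector(s["y", "u2", , ]), rep(0, 4))
  # quadratic map at u = 1, h = 0.05: DY = 0.1025, s = 2.05 (hand value)
  y0 <- 1; h <- 0.05
  dy <- abs((1 + h)^2 - y0) / y0
  expect_equal(dy / h, 2.05)
})

test_that("sensitivity aggregation matches hand-computed RMS and error weights", {
  # constant tensor -> RMS 1; values {3,4} -> sqrt((9+16)/2)
  expect_equal(rms(c(1, 1, 1, 1)), 1)
  expect_equal(rms(c(3, 4)), sqrt(25 / 2), tolerance = 1e-12)

  # E_i1 = 0.1, E_i2 = 0.3 (K = 2): E_iT = 0.2, P = {0.25, 0.75}
  yexp <- matrix(c(10, 10), 1, 2, dimnames = list("y", NULL))
  ysim0 <- matrix(c(9, 7), 1, 2, dimnames = list("y", NULL))  # errors .1/.3
  s <- array(1, dim = c(1, 2, 4, 2),
             dimnames = list("y", c("u1", "u2"), NULL, NULL))
  agg <- aggregate_sensitivities(s, yexp, ysim0)
  expect_equal(unname(agg$E_iT), 0.2)
  expect_equal(unname(agg$P_ik[1, ]), c(0.25, 0.75))
  expect_equal(sum(agg$P_ik[1, ]), 1)
})

test_that("error weights sum to one for any nonzero error table", {
  set.seed(9)
  for (rep in 1:10) {
    n_i <- sample(2:6, 1); n_k <- sample(2:5, 1); n_j <- 3
    yexp <- matrix(runif(n_i * n_k, 5, 50), n_i, n_k,
                   dimnames = list(paste0("y", 1:n_i), NULL))
    ysim0 <- yexp * (1 + matrix(rnorm(n_i * n_k, 0, 0.1), n_i, n_k))
    s <- array(abs(rnorm(n_i * n_j * 4 * n_k)) + 0.01,
               dim = c(n_i, n_j, 4, n_k),
               dimnames = list(paste0("y", 1:n_i), paste0("u", 1:n_j),
                               NULL, NULL))
    agg <- aggregate_sensitivities(s, yexp, ysim0)
    expect_equal(unname(rowSums(agg$P_ik)), rep(1, n_i), tolerance = 1e-12)
    expect_equal(sum(agg$P_i), 1, tolerance = 1e-12)
  }
})

test_that("screening is invariant to a variable's unit rescaling", {
  fx <- minicr_fixture(n_subjects = 4, noise = noise_model(0, 0.04))
  sc1 <- screen_parameters(fx$model, fx$dataset)
  # rescale HR observations by 10 (unit change), and rescale the
  # simulated values consistently via a wrapper dataset
  ds2 <- fx$dataset
  idx <- ds2$observations$variable == "HR"
  ds2$observations$value[idx] <- ds2$observations$value[idx] * 10
  # s_ijlk itself is computed from simulations only and is scale-free;
  # the error weights use relative errors, so a consistent rescaling of
  # y_exp and y_sim leaves them unchanged. Here we rescale only y_exp,
  # so P weights change; the sensitivity tensor must stay identical.
  sc2 <- screen_parameters(fx$model, ds2)
  expect_equal(sc2$sens, sc1$sens)
  # and a *consistent* rescaling leaves the rankings unchanged:
  # relative errors (yexp*c - ysim*c)/(yexp*c) are scale-free by algebra
  yexp <- cohort_means(fx$dataset)[fx$dataset$variables, ]
  ysim <- simulate_steady_state(fx$model, NULL,
                                fx$protocol)$values[fx$dataset$variables, ]
  e1 <- abs((yexp - ysim) / yexp)
  e2 <- abs((10 * yexp - 10 * ysim) / (10 * yexp))
  expect_equal(e1, e2)
})

test_that("full screening returns consistently indexed tensors", {
  fx <- minicr_fixture(n_subjects = 4, noise = noise_model(0, 0.04))
  sc <- screen_parameters(fx$model, fx$dataset)
  n_cand <- length(sc$candidates)
  expect_equal(dim(sc$sens),
               c(length(sc$variables), n_cand, 4, 3))
  expect_equal(sort(names(sc$subset$Z)), sort(sc$candidates))
  expect_equal(sort(names(sc$agg$s_j)), sort(sc$candidates))
  expect_true(all(sc$sens >= 0))
  expect_true(all(sc$subset$Z >= 0))
})
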