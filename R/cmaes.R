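# Covariance matrix adaptation evolution strategy (CMA-ES) with box
# constraints, written for the staged-fitting engine. Standard
# (mu/mu_w, lambda) formulation: weighted recombination, cumulative step
# size adaptation, rank-one and rank-mu covariance updates. Box
# constraints are handled by projection repair: candidates are clipped
# into the box before evaluation and the repaired point enters the
# updates, so every reported solution is feasible. Restarts are local:
# each restart re-centres on the best-ever point with a halved initial
# step size.

#' Minimize a function with CMA-ES under box constraints
#'
#' @param fn Objective `function(x)` returning a scalar (may return `Inf`
#'   for failed evaluations).
#' @param x0 Initial mean (numeric vector).
#' @param lower,upper Box bounds (vectors or scalars).
#' @param sigma0 Initial coordinate-wise standard deviation as a fraction
#'   of the box range (default 0.2).
#' @param pop_size Population size lambda (default `4 + floor(3 ln N)`).
#' @param tol_fun Termination tolerance on the function value spread
#'   (default 1e-12).
#' @param tol_x Termination tolerance on the search distribution spread
#'   relative to the box range (default 1e-3).
#' @param max_iter Iteration cap per restart (default `100 * N^2`).
#' @param max_fun_eval Function-evaluation budget per restart (default
#'   500).
#' @param max_restart Number of restarts after the first run (default 10).
#' @param seed Integer seed (mandatory for reproducibility).
#' @return List: `par` (best-ever feasible point), `value`, `counteval`,
#'   `restarts`, `trace` (best value after each restart).
#' @export
cma_es_min <- function(fn, x0, lower, upper, sigma0 = 0.2,
                       pop_size = NULL, tol_fun = 1e-12, tol_x = 1e-3,
                       max_iter = NULL, max_fun_eval = 500,
                       max_restart = 10, seed) {
  n <- length(x0)
  lower <- rep_len(lower, n)
  upper <- rep_len(upper, n)
  range <- upper - lower
  stopifnot(all(range > 0))
  set.seed(seed)
  lambda <- pop_size %||% (4L + floor(3 * log(n)))
  lambda <- max(4L, as.integer(lambda))
  max_iter <- max_iter %||% (100 * n^2)

  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  clip <- function(x) pmin(pmax(x, lower), upper)
  best_x <- clip(x0)
  best_f <- fn(best_x)
  counteval <- 1L
  trace <- numeric(0)

  for (run in 0:max_restart) {
    m <- if (run == 0) clip(x0) else best_x
    sigma <- sigma0 * mean(range) * (0.5^run)
    sigma_init <- sigma
    pc <- ps <- numeric(n)
    C <- diag(n)
    eig <- list(vectors = diag(n), values = rep(1, n))
    inv_sqrt_c <- diag(n)
    evals_run <- 0L
    f_hist <- c()

    for (iter in seq_len(max_iter)) {
      if (evals_run + lambda > max_fun_eval) break
      z <- matrix(stats::rnorm(n * lambda), nrow = n)
      y <- eig$vectors %*% (sqrt(pmax(eig$values, 0)) * z)
      xs <- m + sigma * y
      xr <- apply(xs, 2, clip)
      if (n == 1L) xr <- matrix(xr, nrow = 1)
      fs <- apply(xr, 2, fn)
      evals_run <- evals_run + lambda
      counteval <- counteval + lambda
      ord <- order(fs)
      if (fs[ord[1]] < best_f) {
        best_f <- fs[ord[1]]
        best_x <- xr[, ord[1]]
      }
      # recombination uses the repaired points
      sel <- xr[, ord[seq_len(mu)], drop = FALSE]
      m_old <- m
      m <- as.vector(sel %*% w)
      y_w <- (m - m_old) / sigma
      ps <- (1 - cs) * ps +
        sqrt(cs * (2 - cs) * mueff) * as.vector(inv_sqrt_c %*% y_w)
      hsig <- as.numeric(
        sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * evals_run / lambda)) /
          chi_n < 1.4 + 2 / (n + 1))
      pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * y_w
      artmp <- (sel - m_old) / sigma
      C <- (1 - c1 - cmu) * C +
        c1 * (pc %o% pc + (1 - hsig) * cc * (2 - cc) * C) +
        cmu * artmp %*% diag(w, nrow = mu) %*% t(artmp)
      sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chi_n - 1))
      C <- (C + t(C)) / 2
      eig <- eigen(C, symmetric = TRUE)
      eig <- list(vectors = eig$vectors, values = pmax(eig$values, 1e-20))
      inv_sqrt_c <- eig$vectors %*% (1 / sqrt(eig$values) *
                                       t(eig$vectors))
      f_hist <- c(utils::tail(f_hist, 10 + ceiling(30 * n / lambda)),
                  fs[ord[1]])
      # termination: flat fitness or collapsed search distribution
      if (length(f_hist) > 10 &&
          max(f_hist) - min(f_hist) < tol_fun) break
      # TolX is read relative to the run's initial step size, so later
      # (halved-sigma) restarts refine further before stopping
      if (sigma * sqrt(max(eig$values)) < tol_x * sigma_init ||
          sigma * sqrt(max(eig$values)) < .Machine$double.eps) break
      if (!all(is.finite(C))) break
    }
    trace <- c(trace, best_f)
  }
  list(par = best_x, value = best_f, counteval = counteval,
       restarts = max_restart, trace = trace)
}
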