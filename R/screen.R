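# Parameter screening: two complementary classification techniques run over
# a grid of stimulus levels and parameter perturbations.
#
#  * Subset selection ranks parameters by how well-conditioned their joint
#    estimation is: SVD of the residual Jacobian at each (level, variation),
#    numerical rank from the normalized singular values, pivoted QR on the
#    leading right singular vectors to order the parameters, then RMS
#    aggregation over levels and variations into a single score Z_j.
#
#  * Sensitivity analysis ranks parameters by error-weighted relative
#    sensitivity of the steady-state outputs: the per-variation sensitivity
#    is RMS-aggregated over variations, normalized and weighted by the
#    nominal model's prediction-error share at each stimulus level (P_ik)
#    and variable (P_i), then RMS-aggregated into per-variable scores s_ij
#    and a total score s_j.

#' Define a perturbation grid
#'
#' Signed fractional parameter variations around the nominal value. The
#' default grid is five variations uniformly distributed over +/-5%:
#' \{-5\%, -2.5\%, 0, +2.5\%, +5\%\}, with 0 serving as the implicit
#' nominal reference (a zero variation makes the relative-sensitivity
#' weighting 1/|h| undefined, so only the four nonzero points enter the
#' tensors).
#'
#' @param h Nonzero signed fractions, at least one positive and one
#'   negative, all |h| <= 1.
#' @return A `pf_grid` object.
#' @export
perturbation_grid <- function(h = c(-0.05, -0.025, 0.025, 0.05)) {
  if (any(h == 0)) stop_pf("perturbation grid must not contain 0")
  if (any(abs(h) > 1)) stop_pf("perturbation fractions must satisfy |h| <= 1")
  if (!any(h > 0) || !any(h < 0)) {
    stop_pf("grid needs at least one positive and one negative variation")
  }
  structure(list(h = as.numeric(h)), class = "pf_grid")
}

#' Residual Jacobian at one stimulus level and variation
#'
#' Finite-difference derivative of the residuals r_i = y_exp,i - y_sim,i
#' with respect to each candidate parameter, with every candidate held at
#' its variation-`h` value (u = (1 + h) * nominal) as the expansion point.
#' The experimental reference is the cohort mean at the level, so the
#' derivative equals minus the simulation derivative; the dataset fixes the
#' residual sign convention and the variable set.
#'
#' @param model A `pf_model`.
#' @param dataset A `pf_dataset` supplying cohort-mean observations.
#' @param params Full parameter vector at which candidates are centred
#'   (default registry nominals).
#' @param level Stimulus level index (1-based).
#' @param h Signed fractional variation applied to every candidate before
#'   differentiating (0 = nominal expansion point).
#' @param candidates Candidate parameter names (default [role_filter()]).
#' @param fd_step Relative forward-difference step (default 1e-6; absolute
#'   floor 1e-9).
#' @return Matrix (variables x candidates) of residual derivatives.
#' @export
residual_jacobian <- function(model, dataset, params = NULL, level, h = 0,
                              candidates = NULL, fd_step = 1e-6) {
  p0 <- full_params(model, params)
  candidates <- candidates %||% role_filter(model$registry)
  vars <- intersect(model_variables(model, fitting = TRUE),
                    dataset$variables)
  proto <- dataset$protocol
  level_proto <- stimulus_protocol(proto$vo2[level], proto$vco2[level],
                                   proto$step_duration,
                                   proto$settle_window)
  base <- p0
  base[candidates] <- base[candidates] * (1 + h)
  sim_at <- function(p) {
    out <- tryCatch(simulate_steady_state(model, p, level_proto),
                    error = function(e) {
                      stop_pf("simulation failed while differentiating (",
                              conditionMessage(e), ")")
                    })
    out$values[vars, 1]
  }
  y0 <- sim_at(base)
  jac <- matrix(NA_real_, nrow = length(vars), ncol = length(candidates),
                dimnames = list(vars, candidates))
  for (j in seq_along(candidates)) {
    pj <- candidates[j]
    delta <- max(fd_step * abs(base[[pj]]), 1e-9)
    pp <- base
    pp[[pj]] <- pp[[pj]] + delta
    yj <- tryCatch(sim_at(pp), error = function(e) {
      stop_pf("simulation failed for parameter '", pj, "' at step ", delta)
    })
    # r = y_exp - y_sim, y_exp constant => dr/du = -dy_sim/du
    jac[, j] <- -(yj - y0) / delta
  }
  jac
}

#' Subset-selection ranking from residual Jacobians
#'
#' For each (level, variation) Jacobian: SVD; numerical rank rho = the
#' number of normalized singular values above `eps`; pivoted QR of the
#' transposed leading right singular vectors orders the parameters; the
#' parameter at pivot position p is assigned the normalized singular value
#' sigma_p / sigma_1 (positions beyond the available singular values get
#' 0). The per-(level, variation) assignments are RMS-aggregated over
#' levels (Z_jl) and then variations (Z_j); the final ranking is Z_j
#' descending, ties broken by candidate order.
#'
#' @param jacobians Nested list: `jacobians[[l]][[k]]` is the Jacobian for
#'   variation l and level k (equal column names across all entries).
#' @param eps Rank tolerance (default 1e-6, the square root of the
#'   optimizer's function-evaluation termination tolerance).
#' @return List with `Z` (named, ranking order), `Z_jl` (params x
#'   variations), `Z_jkl` (params x levels x variations), `rho` (levels x
#'   variations), `orderings` and `eps`.
#' @export
subset_selection_rank <- function(jacobians, eps = 1e-6) {
  stopifnot(eps > 0)
  n_l <- length(jacobians)
  n_k <- length(jacobians[[1L]])
  candidates <- colnames(jacobians[[1L]][[1L]])
  w <- length(candidates)
  z_jkl <- array(NA_real_, dim = c(w, n_k, n_l),
                 dimnames = list(candidates, NULL, NULL))
  rho_kl <- matrix(NA_integer_, nrow = n_k, ncol = n_l)
  orderings <- vector("list", n_l)
  for (l in seq_len(n_l)) {
    orderings[[l]] <- vector("list", n_k)
    for (k in seq_len(n_k)) {
      jac <- jacobians[[l]][[k]]
      if (!all(is.finite(jac))) stop_pf("non-finite Jacobian at (k=", k,
                                        ", l=", l, ")")
      sv <- svd(jac)
      if (sv$d[1] == 0) {
        stop_pf("all-zero Jacobian at (k=", k, ", l=", l,
                "): no identifiable parameter")
      }
      sig_n <- sv$d / sv$d[1]
      rho <- max(which(sig_n > eps))
      v_rho <- sv$v[, seq_len(rho), drop = FALSE]
      # pivot on the singular-value-weighted right singular vectors
      # (pivoted QR of the rank-rho approximation of the Jacobian): the
      # unweighted V_rho^T has unit-norm columns whenever rho equals the
      # parameter count, which would leave the pivot order arbitrary
      qrp <- qr(sv$d[seq_len(rho)] * t(v_rho), LAPACK = TRUE)
      pivot <- qrp$pivot
      vals <- numeric(w)
      vals[pivot] <- c(sig_n, numeric(w))[seq_len(w)]
      z_jkl[, k, l] <- vals
      rho_kl[k, l] <- rho
      orderings[[l]][[k]] <- candidates[pivot]
    }
  }
  z_jl <- apply(z_jkl, c(1, 3), rms)   # RMS over levels
  z_j <- apply(z_jl, 1, rms)           # RMS over variations (final Z_j)
  ord <- order(-z_j)                   # stable: ties keep registry order
  list(Z = z_j[ord], Z_jl = z_jl, Z_jkl = z_jkl, rho = rho_kl,
       orderings = orderings, eps = eps)
}

#' Relative steady-state sensitivity tensor
#'
#' s_ijlk = |Y_ik((1+h_l) u_j) - Y_ik(u)| / |Y_ik(u)| * 1/|h_l|, computed
#' one parameter at a time with all others at their nominal values. The
#' 1/|h_l| factor weights slight variations more heavily.
#'
#' @param model A `pf_model`.
#' @param params Full parameter vector (default nominals).
#' @param protocol A `pf_protocol` whose levels form the k index.
#' @param grid A [perturbation_grid()].
#' @param candidates Candidate parameter names (default [role_filter()]).
#' @param variables Variables to evaluate (default the model's fitting set).
#' @return Array s[variable, parameter, variation, level], all entries >= 0.
#' @export
relative_sensitivity_tensor <- function(model, params = NULL, protocol,
                                        grid = perturbation_grid(),
                                        candidates = NULL,
                                        variables = NULL) {
  p0 <- full_params(model, params)
  candidates <- candidates %||% role_filter(model$registry)
  variables <- variables %||% model_variables(model, fitting = TRUE)
  h <- grid$h
  y0 <- simulate_steady_state(model, p0, protocol)$values[variables, ,
                                                          drop = FALSE]
  degenerate <- abs(y0) < 1e-12
  if (any(degenerate)) {
    idx <- which(degenerate, arr.ind = TRUE)
    stop_pf("nominal steady state below 1e-12 for: ",
            paste(sprintf("(%s, level %d)", variables[idx[, 1]], idx[, 2]),
                  collapse = ", "))
  }
  k <- n_levels(protocol)
  s <- array(NA_real_,
             dim = c(length(variables), length(candidates), length(h), k),
             dimnames = list(variables, candidates, NULL, NULL))
  for (j in seq_along(candidates)) {
    for (l in seq_along(h)) {
      pp <- p0
      pp[[candidates[j]]] <- pp[[candidates[j]]] * (1 + h[l])
      yy <- simulate_steady_state(model, pp, protocol)$values[variables, ,
                                                              drop = FALSE]
      s[, j, l, ] <- abs(yy - y0) / abs(y0) / abs(h[l])
    }
  }
  s
}

#' Aggregate a sensitivity tensor into error-weighted rankings
#'
#' Aggregation chain: s_ijk = RMS over variations of s_ijlk; per-level
#' weights P_ik = E_ik / (K * E_iT) from the nominal model's absolute
#' relative errors E_ik (so that the weights sum to 1 over levels);
#' s_ij = RMS over levels of P_ik * s_ijk / max_j' s_ij'k; per-variable
#' weights P_i = E_i / (I * E_T) from the mean squared relative errors
#' (summing to 1 over variables); s_j = RMS over variables of
#' P_i * s_ij / max_j' s_ij'.
#'
#' @param s Sensitivity array from [relative_sensitivity_tensor()].
#' @param yexp Cohort-mean observation matrix (variables x levels) aligned
#'   with `s`.
#' @param ysim0 Nominal-model steady-state matrix (variables x levels).
#' @return List with `s_ijk`, `s_ij`, `s_j` (ranking order), `P_ik`, `P_i`,
#'   `E_ik`, `E_iT`, `E_i`, `E_T`.
#' @export
aggregate_sensitivities <- function(s, yexp, ysim0) {
  variables <- dimnames(s)[[1]]
  candidates <- dimnames(s)[[2]]
  yexp <- yexp[variables, , drop = FALSE]
  ysim0 <- ysim0[variables, , drop = FALSE]
  if (any(yexp == 0)) stop_pf("zero experimental value in error weighting")
  n_k <- dim(s)[4]
  n_i <- length(variables)

  # per-(variable, level) error weights; a variable with zero total error
  # (perfect nominal fit) gets uniform weights so the sums stay 1
  e_ik <- abs((yexp - ysim0) / yexp)
  e_it <- rowMeans(e_ik)
  p_ik <- e_ik / (n_k * e_it)
  p_ik[e_it == 0, ] <- 1 / n_k

  # per-variable error weights (squared-error form)
  e_i <- rowMeans(((yexp - ysim0) / yexp)^2)
  e_t <- mean(e_i)
  p_i <- if (e_t == 0) rep(1 / n_i, n_i) else e_i / (n_i * e_t)
  names(p_i) <- variables

  # RMS over variations
  s_ijk <- apply(s, c(1, 2, 4), rms)

  # normalize within each (variable, level) slice; drop degenerate slices
  s_ij <- matrix(NA_real_, n_i, length(candidates),
                 dimnames = list(variables, candidates))
  for (i in seq_len(n_i)) {
    terms <- matrix(NA_real_, length(candidates), n_k)
    keep <- rep(TRUE, n_k)
    for (k in seq_len(n_k)) {
      mx <- max(s_ijk[i, , k])
      if (mx == 0) {
        warn_pf("all-zero sensitivity slice (variable ", variables[i],
                ", level ", k, ") excluded from aggregation")
        keep[k] <- FALSE
        next
      }
      terms[, k] <- p_ik[i, k] * s_ijk[i, , k] / mx
    }
    s_ij[i, ] <- apply(terms[, keep, drop = FALSE], 1, rms)
  }

  # total sensitivity across variables
  smax_i <- apply(s_ij, 1, max)
  norm <- sweep(s_ij, 1, smax_i, "/") * p_i
  s_j <- apply(norm, 2, rms)
  s_j <- s_j[order(-s_j)]

  list(s_ijk = s_ijk, s_ij = s_ij, s_j = s_j,
       P_ik = p_ik, P_i = p_i,
       E_ik = e_ik, E_iT = e_it, E_i = e_i, E_T = e_t)
}

#' Run the full screening step
#'
#' Builds residual Jacobians over every (level, variation) pair, runs
#' subset selection, computes the relative-sensitivity tensor and its
#' error-weighted aggregation, and collects everything in a
#' `pf_screening` object.
#'
#' @param model A `pf_model`.
#' @param dataset A `pf_dataset` (cohort means are the error reference).
#' @param params Parameter vector at which to screen (default nominals).
#' @param grid A [perturbation_grid()].
#' @param eps Subset-selection rank tolerance.
#' @param fd_step Forward-difference step for the Jacobians.
#' @return A `pf_screening` list: `candidates`, `subset` (Z ranking and
#'   intermediates), `sens` (tensor), `agg` (weighted rankings and error
#'   weights), `grid`, `eps`.
#' @export
screen_parameters <- function(model, dataset, params = NULL,
                              grid = perturbation_grid(), eps = 1e-6,
                              fd_step = 1e-6) {
  p0 <- full_params(model, params)
  candidates <- role_filter(model$registry)
  proto <- dataset$protocol
  vars <- intersect(model_variables(model, fitting = TRUE),
                    dataset$variables)
  jacobians <- lapply(grid$h, function(h) {
    lapply(seq_len(n_levels(proto)), function(k) {
      residual_jacobian(model, dataset, p0, level = k, h = h,
                        candidates = candidates, fd_step = fd_step)
    })
  })
  subset <- subset_selection_rank(jacobians, eps = eps)
  s <- relative_sensitivity_tensor(model, p0, proto, grid,
                                   candidates = candidates,
                                   variables = vars)
  ysim0 <- simulate_steady_state(model, p0, proto)$values[vars, ,
                                                          drop = FALSE]
  yexp <- cohort_means(dataset, vars)
  agg <- aggregate_sensitivities(s, yexp, ysim0)
  structure(list(candidates = candidates, subset = subset, sens = s,
                 agg = agg, grid = grid, eps = eps, variables = vars),
            class = "pf_screening")
}

#' @export
print.pf_screening <- function(x, ...) {
  cat("Screening of", length(x$candidates), "candidate parameters\n")
  cat("subset-selection ranking (Z_j):\n")
  print(signif(utils::head(x$subset$Z, 10), 3))
  cat("total-sensitivity ranking (s_j):\n")
  print(signif(utils::head(x$agg$s_j, 10), 3))
  invisible(x)
}

#' Export screening rankings as tidy text
#'
#' Writes `parameter, score, rank` tables for both rankings and a JSON
#' bundle with every intermediate tensor.
#'
#' @param screening A `pf_screening`.
#' @param dir Output directory (created if needed).
#' @export
write_screening <- function(screening, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("Z", "s_j")) {
    v <- if (nm == "Z") screening$subset$Z else screening$agg$s_j
    utils::write.table(
      data.frame(parameter = names(v), score = as.numeric(v),
                 rank = seq_along(v)),
      file.path(dir, paste0("ranking_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(
    list(candidates = screening$candidates,
         Z = as.list(screening$subset$Z),
         Z_jl = screening$subset$Z_jl,
         rho = screening$subset$rho,
         s_ijk = screening$agg$s_ijk,
         s_ij = screening$agg$s_ij,
         s_j = as.list(screening$agg$s_j),
         P_ik = screening$agg$P_ik, P_i = as.list(screening$agg$P_i),
         E_ik = screening$agg$E_ik, E_T = screening$agg$E_T,
         eps = screening$eps, h = screening$grid$h),
    file.path(dir, "screening.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
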