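# Parameter selection: four approaches applied to the screening results.
#  1. Standardization pins covariate-role parameters to dataset values.
#  2. Base selection: subset-selection criterion (Z_j > eps) plus a walk of
#     the total-sensitivity ranking until every subsystem is covered.
#  3. Specific selection: one parameter per variable, maximizing a
#     specificity score (high sensitivity for the variable, low for
#     unrelated ones).
#  4. Stimulus-related selection: one parameter per (mechanism, regulatory
#     activity) not already taken.

#' Candidate parameters by role
#'
#' Returns the gain/threshold parameters of the registry, minus excluded
#' and standardization-fixed ones. Time constants and initial values are
#' discarded because fitting targets the steady state; conversion
#' parameters need no fitting; covariates are routed to standardization
#' only.
#'
#' @param registry A `pf_registry`.
#' @return Character vector of candidate parameter names (registry order).
#' @export
role_filter <- function(registry) {
  registry$name[registry$role == "gain_threshold" &
                  !registry$excluded & !registry$fixed]
}

#' Standardize simulation conditions from a dataset
#'
#' Sets every covariate-role parameter to the value the dataset records
#' for it (direct equivalence) and marks it fixed for all later stages.
#'
#' @param registry A `pf_registry`.
#' @param dataset A `pf_dataset` carrying `covariates`.
#' @return List: `values` (named vector of standardized values) and
#'   `registry` (with those parameters flagged fixed).
#' @export
standardize <- function(registry, dataset) {
  covr <- registry$name[registry$role == "covariate"]
  missing <- setdiff(covr, names(dataset$covariates))
  if (length(missing)) {
    stop_pf("covariate(s) missing from dataset: ",
            paste(missing, collapse = ", "))
  }
  values <- vapply(covr, function(nm) dataset$covariates[[nm]], numeric(1))
  registry$nominal[match(covr, registry$name)] <- values
  registry$fixed[match(covr, registry$name)] <- TRUE
  list(values = values, registry = registry)
}

#' Select the base fitting set
#'
#' Union of (a) parameters whose subset-selection score Z_j exceeds the
#' rank tolerance `eps` and (b) parameters taken from the total-sensitivity
#' ranking s_j in descending order, skipping parameters of subsystems that
#' are already covered, until every subsystem with at least one candidate
#' has a selected parameter.
#'
#' @param screening A `pf_screening`.
#' @param eps Tolerance for the subset criterion (default: the screening's
#'   own eps).
#' @param registry The model registry (provides subsystem membership).
#' @return Character vector of base-set parameter names, with a
#'   `provenance` attribute saying which rule admitted each.
#' @export
select_base <- function(screening, eps = NULL, registry) {
  eps <- eps %||% screening$eps
  z <- screening$subset$Z
  subs_of <- stats::setNames(registry$subsystem, registry$name)
  candidates <- screening$candidates
  need <- unique(subs_of[candidates])
  # a subsystem whose gain/threshold parameters all vanished (excluded or
  # standardized) cannot be covered at all
  gain_subs <- unique(registry$subsystem[registry$role == "gain_threshold"])
  dead <- setdiff(gain_subs, need)
  if (length(dead)) {
    stop_pf("subsystem(s) with no candidate parameters: ",
            paste(dead, collapse = ", "))
  }

  admitted <- names(z)[z > eps]
  prov <- stats::setNames(rep("subset: Z_j > eps", length(admitted)),
                          admitted)
  covered <- unique(subs_of[admitted])
  for (pj in names(screening$agg$s_j)) {
    if (length(setdiff(need, covered)) == 0L) break
    if (pj %in% admitted) next
    if (subs_of[[pj]] %in% covered) next
    admitted <- c(admitted, pj)
    prov[pj] <- "sensitivity: subsystem coverage"
    covered <- unique(c(covered, subs_of[[pj]]))
  }
  still <- setdiff(need, covered)
  if (length(still)) {
    warn_pf("no parameter found to cover subsystem(s): ",
            paste(still, collapse = ", "))
  }
  # report in registry order for stable downstream behaviour
  out <- candidates[candidates %in% admitted]
  attr(out, "provenance") <- prov[out]
  out
}

#' Select the specific fitting set
#'
#' One parameter per variable, chosen to maximize a specificity score:
#' per-variable normalized sensitivity minus the largest normalized
#' sensitivity the parameter shows for any variable outside the related
#' set (same subsystem or declared controller/system adjacency). Base-set
#' parameters and parameters of unrelated subsystems are removed first. A
#' parameter may serve only one variable; conflicts are resolved in favour
#' of the higher specificity score and the loser takes its next candidate.
#'
#' @param screening A `pf_screening`.
#' @param base_set Parameters already taken by the base stage.
#' @param model The `pf_model` (provides variable subsystems and the
#'   relatedness adjacency).
#' @return Named character vector: `specific_set[variable] = parameter`.
#'   Variables with no admissible candidate are dropped with a warning.
#' @export
select_specific <- function(screening, base_set, model) {
  s_ij <- screening$agg$s_ij
  variables <- rownames(s_ij)
  reg <- model$registry
  subs_of <- stats::setNames(reg$subsystem, reg$name)
  var_subs <- stats::setNames(model$variables$subsystem,
                              model$variables$name)[variables]
  related <- model$related

  # normalize sensitivities to [0, 1] within each variable
  s_norm <- sweep(s_ij, 1, apply(s_ij, 1, max), "/")

  allowed_subs <- lapply(variables, function(v) {
    unique(c(var_subs[[v]], related[[var_subs[[v]]]]))
  })
  names(allowed_subs) <- variables
  related_vars <- lapply(variables, function(v) {
    variables[var_subs[variables] %in% allowed_subs[[v]]]
  })
  names(related_vars) <- variables

  score <- function(v, pj) {
    others <- setdiff(variables, related_vars[[v]])
    cross <- if (length(others)) max(s_norm[others, pj]) else 0
    s_norm[v, pj] - cross
  }

  cand_lists <- lapply(variables, function(v) {
    ok <- setdiff(colnames(s_ij), base_set)
    # the floor keeps out parameters whose apparent sensitivity is only
    # fixed-point solver noise (e.g. an inactive saturation bound)
    ok <- ok[subs_of[ok] %in% allowed_subs[[v]] & s_ij[v, ok] > 1e-6]
    if (!length(ok)) return(character(0))
    sc <- vapply(ok, function(pj) score(v, pj), numeric(1))
    ok[order(-sc)]
  })
  names(cand_lists) <- variables

  assignment <- character(0)
  unassigned <- variables
  taken <- character(0)
  repeat {
    proposals <- list()
    for (v in unassigned) {
      cl <- setdiff(cand_lists[[v]], taken)
      if (length(cl)) {
        proposals[[v]] <- list(param = cl[1], score = score(v, cl[1]))
      }
    }
    if (!length(proposals)) break
    progressed <- FALSE
    by_param <- split(names(proposals),
                      vapply(proposals, `[[`, "", "param"))
    for (pj in names(by_param)) {
      vs <- by_param[[pj]]
      scores <- vapply(vs, function(v) proposals[[v]]$score, numeric(1))
      winner <- vs[which.max(scores)]  # ties: first variable in set order
      assignment[winner] <- pj
      taken <- c(taken, pj)
      unassigned <- setdiff(unassigned, winner)
      progressed <- TRUE
    }
    if (!progressed || !length(unassigned)) break
  }
  left <- setdiff(variables, names(assignment))
  if (length(left)) {
    warn_pf("no admissible specific parameter for variable(s): ",
            paste(left, collapse = ", "))
  }
  assignment[variables[variables %in% names(assignment)]]
}

#' Select the stimulus-related fitting set
#'
#' One parameter per (mechanism, regulatory activity) pair among the
#' mechanism-tagged gain/threshold parameters that were not selected in the
#' base or specific stages; when several qualify, the one with the highest
#' total sensitivity s_j. Pairs with no free parameter are skipped with a
#' warning.
#'
#' @param registry A `pf_registry` with mechanism/activity tags.
#' @param base_set,specific_set Parameters taken by earlier stages
#'   (`specific_set` may be the named vector from [select_specific()]).
#' @param s_j Total-sensitivity scores (named; used for tie-breaking).
#' @return Data frame (mechanism, activity, parameter).
#' @export
select_stimulus <- function(registry, base_set, specific_set, s_j = NULL) {
  tagged <- registry[!is.na(registry$mechanism) &
                       registry$role == "gain_threshold" &
                       !registry$excluded & !registry$fixed, , drop = FALSE]
  used <- c(base_set, unname(specific_set))
  out <- list()
  keys <- unique(tagged[, c("mechanism", "activity")])
  for (r in seq_len(nrow(keys))) {
    mech <- keys$mechanism[r]
    act <- keys$activity[r]
    pool <- tagged$name[tagged$mechanism == mech & tagged$activity == act]
    free <- setdiff(pool, used)
    if (!length(free)) {
      warn_pf("mechanism '", mech, "' / activity '", act,
              "': no free parameter (already selected earlier)")
      next
    }
    pick <- if (!is.null(s_j) && any(free %in% names(s_j))) {
      free[order(-s_j[free])][1]
    } else free[1]
    out[[length(out) + 1L]] <- data.frame(mechanism = mech, activity = act,
                                          parameter = pick,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(mechanism = character(0), activity = character(0),
                      parameter = character(0)))
  }
  do.call(rbind, out)
}

#' Build the full selection plan
#'
#' Runs standardization and the three fitted-set selections and checks the
#' disjointness invariant (the base, specific and stimulus sets are
#' pairwise disjoint and contain no excluded or standardized parameter).
#'
#' @param model A `pf_model`.
#' @param dataset A `pf_dataset`.
#' @param screening A `pf_screening` from [screen_parameters()].
#' @param eps Tolerance for the base subset criterion.
#' @return A `pf_plan`: `standardized`, `base_set`, `specific_set`,
#'   `stimulus_set`, `provenance`.
#' @export
build_selection_plan <- function(model, dataset, screening, eps = NULL) {
  std <- standardize(model$registry, dataset)
  base_set <- select_base(screening, eps, model$registry)
  specific_set <- select_specific(screening, base_set, model)
  stimulus_set <- select_stimulus(model$registry, base_set, specific_set,
                                  screening$agg$s_j)
  sets <- list(base = as.character(base_set),
               specific = unname(specific_set),
               stimulus = stimulus_set$parameter)
  all_fitted <- unlist(sets)
  if (anyDuplicated(all_fitted)) {
    stop_pf("internal error: fitted sets are not pairwise disjoint")
  }
  reg <- model$registry
  forbidden <- reg$name[reg$excluded | reg$role == "covariate"]
  if (length(intersect(all_fitted, forbidden))) {
    stop_pf("internal error: excluded/standardized parameter in a fitted set")
  }
  prov <- c(
    stats::setNames(rep("standardized from dataset covariate",
                        length(std$values)), names(std$values)),
    attr(base_set, "provenance"),
    stats::setNames(paste0("specific for ", names(specific_set)),
                    unname(specific_set)),
    stats::setNames(paste0("stimulus: ", stimulus_set$mechanism, " / ",
                           stimulus_set$activity), stimulus_set$parameter)
  )
  structure(list(standardized = std$values, base_set = sets$base,
                 specific_set = specific_set, stimulus_set = stimulus_set,
                 provenance = prov),
            class = "pf_plan")
}

#' @export
print.pf_plan <- function(x, ...) {
  cat("Selection plan\n")
  cat("  standardized:", paste(names(x$standardized), collapse = ", "), "\n")
  cat("  base set    :", paste(x$base_set, collapse = ", "), "\n")
  cat("  specific    :",
      paste(sprintf("%s->%s", names(x$specific_set), x$specific_set),
            collapse = ", "), "\n")
  cat("  stimulus    :", paste(x$stimulus_set$parameter, collapse = ", "),
      "\n")
  invisible(x)
}

#' Percentage reduction of the fitting problem
#'
#' `100 * (1 - n_selected / n_total)`, reported to one decimal with ties
#' rounded away from zero. For the standardization stage `n_selected` is
#' the number of parameters remaining after the stage; for fitting stages
#' it is the size of the stage's free set.
#'
#' @param n_selected Count of parameters in the stage set (or remaining).
#' @param n_total Total registry size.
#' @return Percentage, one decimal.
#' @export
reduction_percent <- function(n_selected, n_total) {
  round_half_away(100 * (1 - n_selected / n_total), 1)
}

#' Serialize a selection plan to JSON
#'
#' @param plan A `pf_plan`.
#' @param path Output path.
#' @export
write_plan <- function(plan, path) {
  jsonlite::write_json(
    list(standardized = as.list(plan$standardized),
         base_set = plan$base_set,
         specific_set = as.list(plan$specific_set),
         stimulus_set = plan$stimulus_set,
         provenance = as.list(plan$provenance)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan
#' @export
read_plan <- function(path) {
  x <- jsonlite::fromJSON(path)
  stim <- x$stimulus_set
  if (is.null(stim) || NROW(stim) == 0L) {
    stim <- data.frame(mechanism = character(0), activity = character(0),
                       parameter = character(0))
  }
  spec <- unlist(x$specific_set)
  if (is.null(spec)) spec <- stats::setNames(character(0), character(0))
  structure(list(standardized = unlist(x$standardized),
                 base_set = as.character(x$base_set),
                 specific_set = spec,
                 stimulus_set = stim,
                 provenance = unlist(x$provenance)),
            class = "pf_plan")
}
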