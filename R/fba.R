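# Flux balance analysis, flux variability and alternate-optima enumeration
# over the bounded simplex backend in lp.R.

#' Solver settings for flux balance analysis
#'
#' @param steady_state_tolerance absolute tolerance on `|S v|` for solution
#'   validation.
#' @param optimality_tolerance tolerance used when comparing objective values
#'   (e.g. among alternate optima).
#' @param activity_tolerance absolute flux below which a reaction is treated
#'   as inactive when comparing solution supports.
#' @return a list of class `fba_settings`.
#' @export
fba_settings <- function(steady_state_tolerance = 1e-9,
                         optimality_tolerance = 1e-9,
                         activity_tolerance = 1e-6) {
  stopifnot(steady_state_tolerance > 0, optimality_tolerance > 0)
  structure(list(steady_state_tolerance = steady_state_tolerance,
                 optimality_tolerance = optimality_tolerance,
                 activity_tolerance = activity_tolerance),
            class = "fba_settings")
}

#' Constrain exchange reactions to a diet
#'
#' Sets the uptake capacity (the negated lower bound, in the export-positive
#' convention) of every exchange reaction to the diet's cap for its
#' metabolite, and to zero for metabolites the diet does not supply.
#' Secretion (the upper bound) is left unconstrained.  Returns a modified
#' copy; the input model is untouched.
#'
#' @param model a `metabolic_model` or `community_model`.
#' @param diet a `diet_spec` (see [diet_spec()]) or a named numeric vector of
#'   uptake caps keyed by exchange-metabolite id (compartment suffixes are
#'   ignored when matching, so `glc` addresses `glc_e` or the lumen species
#'   `glc_u`).
#' @param strict when `TRUE`, a diet metabolite without an exchange reaction
#'   in the model is an error; by default such entries are skipped so one
#'   diet can serve models with different exchange repertoires.
#' @return an object of the same class as `model`.
#' @export
apply_diet <- function(model, diet, strict = FALSE) {
  caps <- if (inherits(diet, "diet_spec")) diet$uptake_caps else diet
  caps <- unlist(caps)
  if (is.null(names(caps)) && length(caps)) stop("diet caps must be named by metabolite id")
  is_comm <- inherits(model, "community_model")
  mm <- as_metabolic_model(model)
  ex_met <- exchange_metabolites(mm)       # exchange rxn id -> metabolite id
  base <- sub("_(e|u|c)$", "", ex_met)
  unknown <- setdiff(names(caps), base)
  if (strict && length(unknown)) {
    stop("diet names metabolite(s) with no exchange reaction: ",
         paste(unknown, collapse = ", "))
  }
  hit <- match(base, names(caps))
  new_cap <- ifelse(is.na(hit), 0, caps[hit])
  idx <- match(names(ex_met), mm$reactions$id)
  mm$reactions$lb[idx] <- -as.numeric(new_cap)
  if (is_comm) { model$model <- mm; model } else mm
}

#' Solve a flux balance analysis problem
#'
#' Maximizes the flux of the objective reaction subject to steady state
#' (`S v = 0`) and the reaction bounds.
#'
#' @param model a `metabolic_model` or `community_model`.
#' @param objective reaction id to maximize; defaults to the model's first
#'   biomass reaction.
#' @param settings an [fba_settings()] object.
#' @return a `flux_vector`: list with `values` (named numeric over all
#'   reactions), `objective_value` and `objective_id`.
#' @export
solve_fba <- function(model, objective = NULL, settings = fba_settings()) {
  mm <- as_metabolic_model(model)
  rxn <- mm$reactions
  if (is.null(objective)) {
    if (!length(mm$biomass_ids)) stop("no objective given and model has no biomass reaction")
    objective <- mm$biomass_ids[[1]]
  }
  j <- match(objective, rxn$id)
  if (is.na(j)) stop("unknown objective reaction: ", objective)
  obj <- numeric(nrow(rxn))
  obj[j] <- 1
  res <- lp_solve(obj, A_eq = as.matrix(mm$stoich), b_eq = rep(0, nrow(mm$stoich)),
                  lb = rxn$lb, ub = rxn$ub, maximize = TRUE)
  if (res$status == "infeasible") {
    stop("FBA problem is infeasible (check diet and basal constraints)")
  }
  if (res$status == "unbounded") {
    stop("FBA objective is unbounded; an exchange or internal reaction is missing a cap")
  }
  v <- stats::setNames(res$x, rxn$id)
  if (!check_steady_state(mm, v, tol = settings$steady_state_tolerance * 1e3)) {
    stop("solver returned a flux vector violating steady state beyond tolerance")
  }
  structure(list(values = v, objective_value = res$objective,
                 objective_id = objective),
            class = "flux_vector")
}

#' @export
print.flux_vector <- function(x, ...) {
  cat("<flux_vector> objective ", x$objective_id, " = ",
      format(x$objective_value), " (", length(x$values), " reactions)\n", sep = "")
  invisible(x)
}

#' Flux variability analysis
#'
#' Minimum and maximum flux of every reaction subject to the objective
#' retaining at least `fraction_of_optimum` of its FBA optimum.
#'
#' @inheritParams solve_fba
#' @param fraction_of_optimum number in `[0, 1]`.
#' @param reactions optional subset of reaction ids to scan.
#' @return data.frame with columns `reaction`, `min`, `max`.
#' @export
flux_variability <- function(model, objective = NULL, fraction_of_optimum = 1,
                             settings = fba_settings(), reactions = NULL) {
  mm <- as_metabolic_model(model)
  sol <- solve_fba(mm, objective, settings)
  rxn <- mm$reactions
  j <- match(sol$objective_id, rxn$id)
  lb <- rxn$lb
  lb[j] <- max(lb[j], fraction_of_optimum * sol$objective_value -
                 settings$optimality_tolerance)
  S <- as.matrix(mm$stoich)
  b0 <- rep(0, nrow(S))
  ids <- if (is.null(reactions)) rxn$id else reactions
  out <- data.frame(reaction = ids, min = NA_real_, max = NA_real_,
                    stringsAsFactors = FALSE)
  for (k in seq_along(ids)) {
    jj <- match(ids[k], rxn$id)
    obj <- numeric(nrow(rxn)); obj[jj] <- 1
    lo <- lp_solve(obj, A_eq = S, b_eq = b0, lb = lb, ub = rxn$ub, maximize = FALSE)
    hi <- lp_solve(obj, A_eq = S, b_eq = b0, lb = lb, ub = rxn$ub, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal") {
      stop("FVA subproblem not optimal for reaction ", ids[k], " (", lo$status, "/", hi$status, ")")
    }
    out$min[k] <- lo$objective
    out$max[k] <- hi$objective
  }
  out
}

#' Enumerate alternate optimal solutions
#'
#' Finds flux vectors that all attain the FBA optimum but differ in their set
#' of active reactions.  The search iteratively excludes previously seen
#' active sets by forcing individual active reactions to zero and re-solving,
#' exploring the resulting tree breadth-first in deterministic reaction
#' order.
#'
#' @inheritParams solve_fba
#' @param max_solutions upper bound on the number of solutions returned.
#' @param max_lps cap on the number of LP solves spent searching.
#' @return list of `flux_vector`s; the first is the plain FBA solution.
#' @export
enumerate_optimal_solutions <- function(model, objective = NULL,
                                        max_solutions = 10,
                                        settings = fba_settings(),
                                        max_lps = 200) {
  mm <- as_metabolic_model(model)
  rxn <- mm$reactions
  first <- solve_fba(mm, objective, settings)
  objective <- first$objective_id
  opt <- first$objective_value
  act_tol <- settings$activity_tolerance
  opt_tol <- settings$optimality_tolerance * max(1, abs(opt))
  active_key <- function(v) paste(which(abs(v) > act_tol), collapse = ",")
  sols <- list(first)
  seen <- active_key(first$values)
  j_obj <- match(objective, rxn$id)
  S <- as.matrix(mm$stoich)
  b0 <- rep(0, nrow(S))
  obj <- numeric(nrow(rxn)); obj[j_obj] <- 1
  queue <- lapply(setdiff(which(abs(first$values) > act_tol), j_obj), function(r) r)
  tried <- character(0)
  n_lp <- 0L
  while (length(queue) && length(sols) < max_solutions && n_lp < max_lps) {
    forced <- queue[[1]]; queue <- queue[-1]
    key <- paste(sort(forced), collapse = ",")
    if (key %in% tried) next
    tried <- c(tried, key)
    lb <- rxn$lb; ub <- rxn$ub
    lb[forced] <- 0; ub[forced] <- 0
    res <- lp_solve(obj, A_eq = S, b_eq = b0, lb = lb, ub = ub, maximize = TRUE)
    n_lp <- n_lp + 1L
    if (res$status != "optimal" || res$objective < opt - opt_tol) next
    v <- stats::setNames(res$x, rxn$id)
    k <- active_key(v)
    if (!(k %in% seen)) {
      seen <- c(seen, k)
      sols[[length(sols) + 1L]] <- structure(
        list(values = v, objective_value = res$objective, objective_id = objective),
        class = "flux_vector")
      for (r in setdiff(which(abs(v) > act_tol), c(j_obj, forced))) {
        queue[[length(queue) + 1L]] <- c(forced, r)
      }
    }
  }
  sols
}
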