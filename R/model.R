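# The metabolic_model container: a stoichiometric network with flux bounds,
# subsystem and organism annotations, and registries for biomass and exchange
# reactions.  The stoichiometric matrix is stored sparse (metabolites x
# reactions, Matrix::dgCMatrix) with dimnames carrying the identifiers.

#' Construct a metabolic model
#'
#' Builds and validates a constraint-based metabolic model from its parts.
#' The sign convention is export-positive throughout: an exchange reaction
#' writes its metabolite out of the system (`m ->`), so positive flux is
#' secretion and an uptake capacity of `c` means a lower bound of `-c`.
#'
#' @param metabolites data.frame with columns `id`, `compartment`, `name`.
#' @param reactions data.frame with columns `id`, `lb`, `ub`, `subsystem`,
#'   `organism`.
#' @param stoich sparse or dense matrix, metabolites (rows) by reactions
#'   (columns); dimnames must match the id columns.
#' @param biomass_ids character vector of biomass reaction ids (one per
#'   organism present).
#' @param exchange_ids character vector of exchange reaction ids; each must
#'   touch exactly one metabolite.
#' @param masses optional named numeric of metabolite masses used for
#'   elemental-consistency checks of generated models.
#' @param name model identifier.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, stoich, biomass_ids,
                            exchange_ids, masses = NULL, name = "model") {
  stoich <- Matrix::Matrix(as.matrix(stoich), sparse = TRUE)
  dimnames(stoich) <- list(metabolites$id, reactions$id)
  m <- structure(
    list(metabolites = metabolites, reactions = reactions, stoich = stoich,
         biomass_ids = as.character(biomass_ids),
         exchange_ids = as.character(exchange_ids),
         masses = masses, name = name, annotations = list()),
    class = "metabolic_model")
  validate_model(m)
  m
}

#' Validate a metabolic model
#'
#' Checks the structural invariants: bounds ordered, stoichiometry referencing
#' declared metabolites, biomass and exchange registries resolving, and
#' exchange reactions touching exactly one metabolite.  Stops with an
#' informative error on the first violation.
#'
#' @param model a `metabolic_model`.
#' @return the model, invisibly.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  rxn <- model$reactions
  met <- model$metabolites
  if (anyDuplicated(rxn$id)) stop("duplicate reaction ids")
  if (anyDuplicated(met$id)) stop("duplicate metabolite ids")
  bad <- which(rxn$lb > rxn$ub)
  if (length(bad)) {
    stop("lower bound exceeds upper bound for reaction(s): ",
         paste(rxn$id[bad], collapse = ", "))
  }
  if (!identical(dim(model$stoich), c(nrow(met), nrow(rxn)))) {
    stop("stoichiometric matrix dimensions do not match metabolite/reaction tables")
  }
  missing_bio <- setdiff(model$biomass_ids, rxn$id)
  if (length(missing_bio)) stop("unknown biomass reaction(s): ",
                                paste(missing_bio, collapse = ", "))
  missing_ex <- setdiff(model$exchange_ids, rxn$id)
  if (length(missing_ex)) stop("unknown exchange reaction(s): ",
                               paste(missing_ex, collapse = ", "))
  if (length(model$exchange_ids)) {
    nnz <- Matrix::colSums(model$stoich[, model$exchange_ids, drop = FALSE] != 0)
    if (any(nnz != 1)) {
      stop("exchange reaction(s) not touching exactly one metabolite: ",
           paste(model$exchange_ids[nnz != 1], collapse = ", "))
    }
  }
  invisible(model)
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$name, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", nrow(x$reactions),
      "   biomass: ", paste(x$biomass_ids, collapse = ", "), "\n", sep = "")
  cat("  exchanges: ", length(x$exchange_ids), "\n", sep = "")
  invisible(x)
}

#' Number of reactions / metabolites
#' @param model a `metabolic_model`.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(as_metabolic_model(model)$reactions)

#' @rdname n_reactions
#' @export
n_metabolites <- function(model) nrow(as_metabolic_model(model)$metabolites)

#' Coerce to a metabolic model
#'
#' Community containers carry their network in `$model`; this generic lets
#' all solver-facing functions accept either form.
#'
#' @param x a `metabolic_model` or `community_model`.
#' @return a `metabolic_model`.
#' @export
as_metabolic_model <- function(x) UseMethod("as_metabolic_model")

#' @export
as_metabolic_model.metabolic_model <- function(x) x

#' @export
as_metabolic_model.community_model <- function(x) x$model

# Exchange metabolite id for each exchange reaction (named character).
exchange_metabolites <- function(model) {
  model <- as_metabolic_model(model)
  if (!length(model$exchange_ids)) return(character(0))
  sub <- model$stoich[, model$exchange_ids, drop = FALSE]
  idx <- apply(sub != 0, 2, which)
  stats::setNames(model$metabolites$id[idx], model$exchange_ids)
}

# Verify a flux vector against steady state and bounds; used as the central
# feasibility validator for everything the package produces.
check_steady_state <- function(model, v, tol = 1e-9) {
  model <- as_metabolic_model(model)
  resid <- max(abs(as.numeric(model$stoich %*% v)))
  in_bounds <- all(v >= model$reactions$lb - tol & v <= model$reactions$ub + tol)
  resid <= tol && in_bounds
}

# Cheap structural fingerprint for provenance records.
model_digest <- function(model) {
  model <- as_metabolic_model(model)
  s <- model$stoich
  sprintf("%s:%dx%d:%.6g", model$name, nrow(s), ncol(s), sum(abs(s)))
}
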