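# Community topologies: the compartmentalized join (two organisms sharing a
# lumen compartment) and the lumped pooled ("supra-organism") model.
#
# Organism tagging appends "__<tag>" to reaction and metabolite ids; "__" is
# reserved and SId-safe.  In a join, each organism's exchange reaction
# becomes a transport between its own extracellular species and a shared
# lumen species ("<met>_u"), and one community-level exchange per lumen
# species connects the lumen to the environment.  Diets applied to the
# joined model therefore constrain only the community exchanges.

TAG_SEP <- "__"

community_model <- function(model, organisms, lumen, id_map) {
  structure(list(model = model, organisms = organisms,
                 lumen_compartment = lumen, id_map = id_map),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> organisms: ", paste(x$organisms, collapse = ", "),
      if (!is.na(x$lumen_compartment)) paste0("  (lumen '", x$lumen_compartment, "')"),
      "\n", sep = "")
  print(x$model)
  invisible(x)
}

# Suffix every id of a model with its tag; returns model plus the id map.
.tag_model <- function(model, tag) {
  sfx <- function(x) paste0(x, TAG_SEP, tag)
  map <- stats::setNames(sfx(model$reactions$id), model$reactions$id)
  model$reactions$id <- unname(map)
  model$reactions$organism <- tag
  model$metabolites$id <- sfx(model$metabolites$id)
  dimnames(model$stoich) <- list(model$metabolites$id, model$reactions$id)
  model$biomass_ids <- unname(map[model$biomass_ids])
  model$exchange_ids <- unname(map[model$exchange_ids])
  if (!is.null(model$masses)) names(model$masses) <- sfx(names(model$masses))
  list(model = model, map = map)
}

#' Join two models through a shared lumen compartment
#'
#' Builds the compartmentalized community model: both organisms' networks are
#' kept intact (ids tagged with the organism), every original exchange
#' reaction is rewired into a transport between the organism's extracellular
#' species and a shared lumen species, and one community exchange per lumen
#' species is added.  Lumen transports are open in both directions; community
#' exchanges start closed for uptake until a diet is applied.
#'
#' @param model_a,model_b `metabolic_model`s.  When the two carry the same
#'   name (a clonal pairing), copy indices are appended to the tags.
#' @return a `community_model`.
#' @export
join_compartmentalized <- function(model_a, model_b) {
  tag_a <- model_a$name
  tag_b <- model_b$name
  if (identical(tag_a, tag_b)) {
    tag_a <- paste0(tag_a, "_1")
    tag_b <- paste0(tag_b, "_2")
  }
  ex_a <- exchange_metabolites(model_a)
  ex_b <- exchange_metabolites(model_b)
  ta <- .tag_model(model_a, tag_a)
  tb <- .tag_model(model_b, tag_b)
  a <- ta$model; b <- tb$model

  lumen_base <- sort(unique(sub("_(e)$", "", c(unname(ex_a), unname(ex_b)))))
  lumen_ids <- paste0(lumen_base, "_u")

  mets <- rbind(a$metabolites, b$metabolites,
                data.frame(id = lumen_ids, compartment = "u", name = lumen_base,
                           stringsAsFactors = FALSE))
  if (anyDuplicated(mets$id)) {
    stop("metabolite id collision after tagging: ",
         paste(mets$id[duplicated(mets$id)], collapse = ", "))
  }
  rxns <- rbind(a$reactions, b$reactions)
  nm <- nrow(mets); nr <- nrow(rxns)
  S <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                            dims = c(nm, nr), dimnames = list(mets$id, rxns$id))
  S[rownames(a$stoich), colnames(a$stoich)] <- a$stoich
  S[rownames(b$stoich), colnames(b$stoich)] <- b$stoich

  # rewire each organism exchange "met_e__tag ->" into a lumen transport
  # "met_e__tag -> met_u" (reversible), and drop it from the exchange set
  rewire <- function(S, ex_map, tag) {
    for (k in seq_along(ex_map)) {
      exid <- paste0(names(ex_map)[k], TAG_SEP, tag)
      base <- sub("_(e)$", "", unname(ex_map)[k])
      S[paste0(base, "_u"), exid] <- 1   # export-positive into the lumen
      j <- match(exid, rxns$id)
      rxns$lb[j] <<- -DEFAULT_BOUND
      rxns$ub[j] <<- DEFAULT_BOUND
      rxns$subsystem[j] <<- "lumen transport"
    }
    S
  }
  S <- rewire(S, ex_a, tag_a)
  S <- rewire(S, ex_b, tag_b)

  # one community exchange per lumen species; uptake closed until a diet opens it
  comm_ex <- paste0("EX_", lumen_base, "_u")
  rxns <- rbind(rxns, data.frame(id = comm_ex, lb = 0, ub = DEFAULT_BOUND,
                                 subsystem = "exchange", organism = NA_character_,
                                 stringsAsFactors = FALSE))
  S <- cbind(S, Matrix::sparseMatrix(i = match(lumen_ids, mets$id),
                                     j = seq_along(comm_ex), x = -1,
                                     dims = c(nm, length(comm_ex)),
                                     dimnames = list(mets$id, comm_ex)))
  joined <- metabolic_model(mets, rxns, S,
                            biomass_ids = c(a$biomass_ids, b$biomass_ids),
                            exchange_ids = comm_ex,
                            masses = c(a$masses, b$masses),
                            name = paste0(tag_a, "+", tag_b))
  community_model(joined, organisms = c(tag_a, tag_b), lumen = "u",
                  id_map = stats::setNames(list(ta$map, tb$map), c(tag_a, tag_b)))
}

#' Inactivate one organism in a community
#'
#' Sets both flux bounds of every reaction tagged with the organism to zero
#' (including its biomass and lumen transports), simulating mono-culture of
#' the partner.  Returns a modified copy; idempotent.
#'
#' @param community a `community_model`.
#' @param organism organism tag to shut off.
#' @return a `community_model`.
#' @export
shut_off <- function(community, organism) {
  stopifnot(inherits(community, "community_model"))
  if (!organism %in% community$organisms) {
    stop("unknown organism tag: ", organism)
  }
  rxn <- community$model$reactions
  sel <- !is.na(rxn$organism) & rxn$organism == organism
  rxn$lb[sel] <- 0
  rxn$ub[sel] <- 0
  community$model$reactions <- rxn
  community
}

# canonical stoichiometry key for consolidation
.stoich_key <- function(S, j) {
  col <- S[, j]
  nz <- which(abs(col) > 1e-12)
  paste(rownames(S)[nz], signif(col[nz], 12), sep = ":", collapse = ";")
}

#' Pool models into a lumped (supra-organism) community
#'
#' Merges all reactions and metabolites of the input models into one
#' single-compartment network, ignoring any separation between cells.
#' Reactions with identical stoichiometry are consolidated to a single copy
#' whose bounds are the interval hull of the merged copies.  Biomass
#' reactions are never consolidated: each input model keeps its own, tagged
#' with the organism, and all appear in `biomass_ids`.
#'
#' @param models list of `metabolic_model`s (length >= 1).
#' @return a `community_model` without a lumen compartment.
#' @export
pool_models <- function(models) {
  stopifnot(length(models) >= 1)
  tags <- vapply(models, function(m) m$name, "")
  if (anyDuplicated(tags)) tags <- paste0(tags, "_", seq_along(tags))
  met_tab <- list(); met_seen <- character(0)
  rxn_rows <- list()
  key_of <- list()      # stoich key -> pooled reaction id
  stoich_of <- list()   # pooled reaction id -> named stoich
  id_map <- stats::setNames(vector("list", length(models)), tags)
  masses <- numeric(0)
  biomass_ids <- character(0)
  exchange_ids <- character(0)
  for (k in seq_along(models)) {
    m <- models[[k]]
    new_mets <- !(m$metabolites$id %in% met_seen)
    met_tab[[k]] <- m$metabolites[new_mets, , drop = FALSE]
    met_seen <- c(met_seen, m$metabolites$id[new_mets])
    if (!is.null(m$masses)) masses <- c(masses, m$masses[!(names(m$masses) %in% names(masses))])
    map <- character(0)
    for (j in seq_len(nrow(m$reactions))) {
      rid <- m$reactions$id[j]
      is_bio <- rid %in% m$biomass_ids
      if (is_bio) {
        pid <- paste0(rid, TAG_SEP, tags[k])
        col <- m$stoich[, j]
        nz <- which(abs(col) > 1e-12)
        stoich_of[[pid]] <- stats::setNames(col[nz], rownames(m$stoich)[nz])
        rxn_rows[[pid]] <- data.frame(id = pid, lb = m$reactions$lb[j],
                                      ub = m$reactions$ub[j],
                                      subsystem = m$reactions$subsystem[j],
                                      organism = tags[k], stringsAsFactors = FALSE)
        biomass_ids <- c(biomass_ids, pid)
      } else {
        key <- .stoich_key(m$stoich, j)
        if (!is.null(key_of[[key]])) {
          pid <- key_of[[key]]
          # interval hull of bounds
          rxn_rows[[pid]]$lb <- min(rxn_rows[[pid]]$lb, m$reactions$lb[j])
          rxn_rows[[pid]]$ub <- max(rxn_rows[[pid]]$ub, m$reactions$ub[j])
          rxn_rows[[pid]]$organism <- NA_character_  # shared
        } else {
          pid <- if (is.null(rxn_rows[[rid]])) rid else paste0(rid, TAG_SEP, tags[k])
          key_of[[key]] <- pid
          col <- m$stoich[, j]
          nz <- which(abs(col) > 1e-12)
          stoich_of[[pid]] <- stats::setNames(col[nz], rownames(m$stoich)[nz])
          rxn_rows[[pid]] <- data.frame(id = pid, lb = m$reactions$lb[j],
                                        ub = m$reactions$ub[j],
                                        subsystem = m$reactions$subsystem[j],
                                        organism = tags[k], stringsAsFactors = FALSE)
          if (rid %in% m$exchange_ids) exchange_ids <- c(exchange_ids, pid)
        }
      }
      map[rid] <- pid
    }
    id_map[[tags[k]]] <- map
  }
  mets <- do.call(rbind, met_tab)
  rxns <- do.call(rbind, unname(rxn_rows))
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (j in seq_len(nrow(rxns))) {
    st <- stoich_of[[rxns$id[j]]]
    ti <- c(ti, match(names(st), mets$id)); tj <- c(tj, rep(j, length(st)))
    tx <- c(tx, unname(st))
  }
  S <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(nrow(mets), nrow(rxns)),
                            dimnames = list(mets$id, rxns$id))
  pooled <- metabolic_model(mets, rxns, S, biomass_ids = biomass_ids,
                            exchange_ids = exchange_ids,
                            masses = if (length(masses)) masses,
                            name = paste0("pool(", paste(tags, collapse = ","), ")"))
  community_model(pooled, organisms = tags, lumen = NA_character_, id_map = id_map)
}
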