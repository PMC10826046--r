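# The quasi-dynamic costless-secretion loop: organisms are simulated
# separately on a shared minimal medium; metabolites secreted at no growth
# cost are added to the medium, and the loop repeats until the medium is
# stable.  In sampling mode, secretion is decided by the fraction of sampled
# flux distributions that secrete the metabolite ("all" = every sample,
# "most" = more than half, "any" = at least one).

COSTLESS_MODES <- c("fba", "all", "most", "any")

#' Initialize a minimal-media costless simulation
#'
#' Closes every uptake except the minimal-media metabolites and the supplied
#' carbon sources; carbon uptake is capped at 10 mmol/gDW/h (growth-limiting
#' by construction), oxygen follows the aerobic flag.
#'
#' @param models list of `metabolic_model`s.
#' @param media named numeric of minimal-media uptake caps (may be empty).
#' @param carbon_sources character vector of carbon-source metabolite ids.
#' @param aerobic logical.
#' @param carbon_cap uptake cap applied to each carbon source (default 10).
#' @return list with `models` (constrained copies) and `media_state`, a
#'   data.frame (metabolite, cap, added_iteration, secreted_by).
#' @export
init_minimal_media <- function(models, media = numeric(0), carbon_sources,
                               aerobic = FALSE, carbon_cap = 10) {
  base <- function(m) sub("_(e|u|c)$", "", m)
  known <- unique(unlist(lapply(models, function(m) base(exchange_metabolites(m)))))
  unknown <- setdiff(carbon_sources, known)
  if (length(unknown)) {
    stop("carbon source(s) without an exchange reaction in any model: ",
         paste(unknown, collapse = ", "))
  }
  caps <- unlist(media)
  caps <- if (length(caps)) caps else stats::setNames(numeric(0), character(0))
  caps[carbon_sources] <- carbon_cap
  caps["o2"] <- if (aerobic) DEFAULT_BOUND else 0
  media_state <- data.frame(metabolite = names(caps), cap = as.numeric(caps),
                            added_iteration = 0L, secreted_by = NA_character_,
                            stringsAsFactors = FALSE)
  constrained <- lapply(models, apply_diet, diet = caps)
  list(models = constrained, media_state = media_state)
}

#' Detect secreted metabolites
#'
#' FBA mode: a metabolite is secreted if its exchange flux exceeds
#' `eps_sec` in the optimal solution (with an ensemble, in the fraction of
#' solutions the threshold mode requires).  Sampling mode: secreted if the
#' fraction of samples with exchange flux above `eps_sec` meets the cutoff
#' (any: > 0, most: > 0.5, all: = 1).
#'
#' @param growth a `flux_vector`, a list of flux vectors, or a
#'   `flux_sample_set`.
#' @param model the model the fluxes belong to.
#' @param mode one of `"fba"`, `"all"`, `"most"`, `"any"`.
#' @param eps_sec secretion detection floor (mmol/gDW/h).
#' @return character vector of secreted metabolite ids (base ids, without
#'   compartment suffix).
#' @export
detect_secretions <- function(growth, model, mode = "fba", eps_sec = 1e-6) {
  mode <- match.arg(mode, COSTLESS_MODES)
  mm <- as_metabolic_model(model)
  ex_met <- exchange_metabolites(mm)
  if (inherits(growth, "flux_vector")) growth <- list(growth)
  V <- if (inherits(growth, "flux_sample_set")) growth$samples
       else do.call(rbind, lapply(growth, function(fv) fv$values))
  frac <- colMeans(V[, names(ex_met), drop = FALSE] > eps_sec)
  sel <- switch(mode,
                fba = frac > 0,   # secreted in the solution / any ensemble member
                all = frac >= 1,
                most = frac > 0.5,
                any = frac > 0)
  unname(sub("_(e|u)$", "", ex_met[sel]))
}

#' Run the costless-secretion loop
#'
#' Iterates grow -> detect secretions -> expand media until no new
#' metabolite is added (or `max_iterations` is reached, in which case the
#' record is flagged unconverged).  Growth is FBA (`mode = "fba"`) or flux
#' sampling with the all/most/any secretion cutoffs; in sampling mode the
#' sampler is re-seeded deterministically as `seed + iteration`.
#'
#' @param models list of `metabolic_model`s (typically two).
#' @param media named numeric minimal-media caps.
#' @param carbon_sources character vector of carbon sources provided.
#' @param aerobic logical.
#' @param mode `"fba"`, `"all"`, `"most"` or `"any"`.
#' @param sampler_settings a [sampler_settings()]; sampling modes only.
#' @param max_iterations loop cap (default 25).
#' @param eps_sec secretion floor.
#' @param added_cap uptake cap given to newly added media metabolites
#'   (default unbounded at the box convention, 1000).
#' @return a `costless_record`: list with `iterations` (per-iteration media,
#'   growth summaries, secreted sets, uptake sets), `media_state`,
#'   `converged_at`, `converged`, `mode`, `carbon_sources`.
#' @export
run_costless <- function(models, media = numeric(0), carbon_sources,
                         aerobic = FALSE, mode = c("fba", "all", "most", "any"),
                         sampler_settings = NULL, max_iterations = 25,
                         eps_sec = 1e-6, added_cap = DEFAULT_BOUND) {
  mode <- match.arg(mode)
  if (mode != "fba" && is.null(sampler_settings)) {
    sampler_settings <- sampler_settings()
  }
  names(models) <- vapply(models, function(m) m$name, "")
  init <- init_minimal_media(models, media, carbon_sources, aerobic)
  media_state <- init$media_state
  iterations <- list()
  converged <- FALSE
  converged_at <- NA_integer_
  for (iter in seq_len(max_iterations)) {
    caps <- stats::setNames(media_state$cap, media_state$metabolite)
    new_secreted <- character(0)
    iter_rec <- list(media = media_state, growth = list(), secreted = list(),
                     uptake = list())
    for (org in names(models)) {
      m <- apply_diet(models[[org]], caps)
      if (mode == "fba") {
        fv <- solve_fba(m)
        growth <- fv$objective_value
        sec <- detect_secretions(fv, m, "fba", eps_sec)
        upt <- .uptaken_metabolites(fv$values, m, eps_sec)
      } else {
        ss <- sampler_settings
        ss$seed <- ss$seed + iter
        samp <- sample_fluxes(m, ss)
        g <- samp$samples[, m$biomass_ids[[1]]]
        growth <- c(median = stats::median(g), min = min(g), max = max(g))
        sec <- detect_secretions(samp, m, mode, eps_sec)
        upt <- .uptaken_metabolites(samp$samples, m, eps_sec)
      }
      iter_rec$growth[[org]] <- growth
      iter_rec$secreted[[org]] <- sec
      iter_rec$uptake[[org]] <- upt
      new_secreted <- union(new_secreted, sec)
    }
    iterations[[iter]] <- iter_rec
    added <- setdiff(new_secreted, media_state$metabolite)
    if (!length(added)) {
      converged <- TRUE
      converged_at <- iter
      break
    }
    secretors <- vapply(added, function(m2) {
      paste(names(models)[vapply(names(models), function(o)
        m2 %in% iter_rec$secreted[[o]], NA)], collapse = "+")
    }, "")
    media_state <- rbind(media_state,
                         data.frame(metabolite = added, cap = added_cap,
                                    added_iteration = iter,
                                    secreted_by = secretors,
                                    stringsAsFactors = FALSE))
  }
  structure(list(iterations = iterations, media_state = media_state,
                 converged = converged, converged_at = converged_at,
                 mode = mode, carbon_sources = carbon_sources,
                 aerobic = aerobic, organisms = names(models)),
            class = "costless_record")
}

# Metabolites with uptake (negative exchange flux) beyond the floor, as base
# ids.  For matrices, any sample taking the metabolite up counts.
.uptaken_metabolites <- function(V, model, eps_sec) {
  mm <- as_metabolic_model(model)
  ex_met <- exchange_metabolites(mm)
  if (is.matrix(V)) {
    sel <- apply(V[, names(ex_met), drop = FALSE] < -eps_sec, 2, any)
  } else {
    sel <- V[names(ex_met)] < -eps_sec
  }
  unname(sub("_(e|u)$", "", ex_met[sel]))
}

#' @export
print.costless_record <- function(x, ...) {
  cat("<costless_record> mode=", x$mode,
      if (x$converged) paste0("  converged at iteration ", x$converged_at)
      else "  NOT converged", "\n", sep = "")
  cat("  media size: ", nrow(x$media_state), " (",
      sum(x$media_state$added_iteration > 0), " added)\n", sep = "")
  invisible(x)
}

#' Label a costless-secretion outcome
#'
#' First letter: N (no cross-feeding: no used media metabolite came from
#' either organism), C (unidirectional exchange) or M (reciprocal exchange).
#' The digit is the number of supplied carbon sources; suffix `a`/`b` marks
#' the absence/presence of competition, operationalized as both organisms
#' taking up a common capped metabolite in the final iteration.  An organism
#' that never grows in any iteration yields the distinguished `"NG"`
#' (no-growth) category.
#'
#' @param record a `costless_record`.
#' @param eps_g absolute growth floor for the no-growth category.
#' @return a single character code, e.g. `"N1a"`, `"C1a"`, `"M2b"` or
#'   `"NG"`.
#' @export
label_costless_interaction <- function(record, eps_g = 1e-6) {
  stopifnot(inherits(record, "costless_record"))
  orgs <- record$organisms
  grew <- vapply(orgs, function(o) {
    any(vapply(record$iterations, function(it) {
      g <- it$growth[[o]]
      max(g) > eps_g
    }, NA))
  }, NA)
  if (any(!grew)) return("NG")
  # cross-feeding edges: metabolite added by X's secretion, taken up by Y != X
  added <- record$media_state[record$media_state$added_iteration > 0, , drop = FALSE]
  edges <- matrix(FALSE, length(orgs), length(orgs),
                  dimnames = list(orgs, orgs))
  for (i in seq_len(nrow(added))) {
    m <- added$metabolite[i]
    secs <- strsplit(added$secreted_by[i], "+", fixed = TRUE)[[1]]
    for (x in secs) for (y in setdiff(orgs, x)) {
      used <- any(vapply(record$iterations, function(it)
        m %in% it$uptake[[y]], NA))
      if (used) edges[x, y] <- TRUE
    }
  }
  ab <- edges[orgs[1], orgs[2]] || FALSE
  ba <- edges[orgs[2], orgs[1]] || FALSE
  letter <- if (ab && ba) "M" else if (ab || ba) "C" else "N"
  # competition: both organisms take up the same capped metabolite at the end
  final <- record$iterations[[length(record$iterations)]]
  capped <- record$media_state$metabolite[record$media_state$cap < DEFAULT_BOUND &
                                          record$media_state$cap > 0]
  shared <- intersect(intersect(final$uptake[[orgs[1]]], final$uptake[[orgs[2]]]),
                      capped)
  suffix <- if (length(shared)) "b" else "a"
  paste0(letter, length(record$carbon_sources), suffix)
}

#' Enumerate a costless-secretion experimental design
#'
#' All unordered organism pairs crossed with aerobic states and carbon
#' sources: the case grid of a costless-secretion campaign.
#'
#' @param models an integer (number of organisms) or list of models.
#' @param carbon_sources character vector (or an integer count) of carbon
#'   sources.
#' @param aerobic_states logical vector of aerobic conditions to cover.
#' @return data.frame with columns `a`, `b`, `aerobic`, `carbon_source`.
#' @export
costless_design <- function(models, carbon_sources,
                            aerobic_states = c(TRUE, FALSE)) {
  pairs <- pair_design(models)
  if (is.numeric(carbon_sources) && length(carbon_sources) == 1) {
    carbon_sources <- paste0("C", seq_len(carbon_sources))
  }
  out <- merge(merge(pairs, data.frame(aerobic = aerobic_states)),
               data.frame(carbon_source = carbon_sources,
                          stringsAsFactors = FALSE))
  out[order(out$a, out$b, out$aerobic, out$carbon_source), c("a", "b", "aerobic", "carbon_source")]
}
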