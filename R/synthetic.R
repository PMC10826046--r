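# Synthetic toy microbes, diets, cross-feeding pairs and communities.
#
# Every generated network follows one template: a sugar is imported and
# catabolized either fermentatively (lower biomass yield, byproducts
# secreted) or respiratorily (oxygen-consuming, higher yield); biomass is a
# single drain on a generic precursor P plus any required nutrients.  All
# non-exchange, non-biomass reactions conserve a declared metabolite mass
# vector, so mass balance of the generators is checkable by construction.
#
# Reserved metabolite ids: "glc" and "fru" (monosaccharides), "fiber" (a
# 4-mer polymer of glc requiring a degradation reaction), "o2" (oxygen),
# "P" (biomass precursor).  Compartments: "e" extracellular, "c" cytosol.

DEFAULT_BOUND <- 1000
FIBER_LENGTH <- 4

#' Specification of a toy microbe
#'
#' @param name organism identifier (also used as the organism tag).
#' @param carbon_sources metabolite ids the organism can consume as carbon;
#'   `"fiber"` additionally grants the polymer degradation reaction.
#' @param secretes named character: byproduct metabolite id -> route
#'   (`"ferment"` or `"respire"`); one unit is secreted per unit substrate
#'   routed through that pathway.
#' @param requires metabolite ids that must be imported for biomass (one unit
#'   per unit growth).
#' @param boosts named numeric: metabolite id -> extra precursor yield when
#'   the metabolite is imported and salvaged (one salvage reaction each).
#' @param converts list of `c(from, to)` pairs: a growth-free conversion of a
#'   carbon source into a secretable metabolite, mass-balanced by ratio.
#' @param aerobic_yield,anaerobic_yield precursor units per substrate via the
#'   respiratory and fermentative route; `aerobic_yield >= anaerobic_yield > 0`.
#' @param uptake_cap transporter capacity for each carbon source
#'   (mmol/gDW/h).
#' @param biomass_p_cost precursor units consumed per unit growth.
#' @param max_growth upper bound on the biomass reaction (h^-1).
#' @param mass_overrides named numeric overriding default metabolite masses
#'   (byproducts default to 0.25, salvaged metabolites to their boost yield).
#' @return a validated list of class `microbe_spec`.
#' @export
microbe_spec <- function(name, carbon_sources = "glc", secretes = NULL,
                         requires = NULL, boosts = NULL, converts = NULL,
                         aerobic_yield = 2, anaerobic_yield = 1,
                         uptake_cap = 10, biomass_p_cost = 1,
                         max_growth = DEFAULT_BOUND, mass_overrides = NULL) {
  if (!(aerobic_yield >= anaerobic_yield && anaerobic_yield > 0)) {
    stop("require aerobic_yield >= anaerobic_yield > 0")
  }
  if (uptake_cap <= 0) stop("uptake_cap must be positive")
  if (length(intersect(names(secretes), requires))) {
    stop("a metabolite cannot be both secreted and required")
  }
  if (!is.null(secretes) && (is.null(names(secretes)) ||
      !all(secretes %in% c("ferment", "respire")))) {
    stop("secretes must be a named character of routes 'ferment'/'respire'")
  }
  structure(list(name = name, carbon_sources = carbon_sources,
                 secretes = secretes, requires = requires, boosts = boosts,
                 converts = converts, aerobic_yield = aerobic_yield,
                 anaerobic_yield = anaerobic_yield, uptake_cap = uptake_cap,
                 biomass_p_cost = biomass_p_cost, max_growth = max_growth,
                 mass_overrides = mass_overrides),
            class = "microbe_spec")
}

#' Specification of a diet
#'
#' @param name identifier.
#' @param uptake_caps named numeric: exchange-metabolite id -> maximum uptake
#'   magnitude (mmol/gDW/h); metabolites not listed are unavailable.
#' @param aerobic logical; when `FALSE` the oxygen cap is forced to zero.
#' @return a list of class `diet_spec`.
#' @export
diet_spec <- function(name, uptake_caps, aerobic = TRUE) {
  caps <- unlist(uptake_caps)
  if (any(caps < 0)) stop("uptake caps must be nonnegative")
  if (!aerobic) caps["o2"] <- 0
  structure(list(name = name, uptake_caps = caps, aerobic = aerobic),
            class = "diet_spec")
}

#' Built-in diet analogs
#'
#' `"sugar"` supplies directly consumable monosaccharides (glc and fru, 10
#' mmol/gDW/h each), a simple-sugar Western-style analog.  `"fiber"` supplies
#' only the polymer (10 mmol/gDW/h), which must be degraded before use;
#' monosaccharide caps are zero.
#'
#' @param kind `"sugar"` or `"fiber"`.
#' @param aerobic logical; oxygen cap is 1000 when aerobic, 0 otherwise.
#' @return a `diet_spec`.
#' @export
make_diet <- function(kind = c("sugar", "fiber"), aerobic = TRUE) {
  kind <- match.arg(kind)
  caps <- switch(kind,
    sugar = c(glc = 10, fru = 10),
    fiber = c(glc = 0, fru = 0, fiber = 10))
  caps["o2"] <- if (aerobic) DEFAULT_BOUND else 0
  diet_spec(paste0(kind, if (aerobic) "_aerobic" else "_anaerobic"),
            caps, aerobic = aerobic)
}

# Default mass assignment for the template (see file header).
.toy_masses <- function(spec) {
  m <- c(P = 1, o2 = 1)
  for (b in names(spec$secretes)) m[b] <- 0.25
  for (x in names(spec$boosts)) m[x] <- as.numeric(spec$boosts[[x]])
  for (r in spec$requires) m[r] <- 1
  if (!is.null(spec$mass_overrides)) m[names(spec$mass_overrides)] <- spec$mass_overrides
  k_f <- sum(m[names(spec$secretes)[spec$secretes == "ferment"]])
  sugar_mass <- spec$anaerobic_yield * m[["P"]] + k_f
  sugars <- setdiff(spec$carbon_sources, "fiber")
  if (!length(sugars)) sugars <- "glc"  # fiber degrades into glc internally
  for (s in sugars) if (!s %in% names(m)) m[s] <- sugar_mass
  if (!"glc" %in% names(m)) m["glc"] <- sugar_mass
  m["fiber"] <- FIBER_LENGTH * m[["glc"]]
  for (cv in spec$converts) if (!cv[["to"]] %in% names(m)) m[cv[["to"]]] <- 0.25
  m
}

#' Build a toy genome-scale model from a microbe specification
#'
#' Deterministically expands a [microbe_spec()] into a mass-balanced
#' `metabolic_model` with one exchange reaction per extracellular metabolite,
#' transporters, a fermentative route (secreting the spec'd byproducts), a
#' respiratory route with higher yield when `aerobic_yield >
#' anaerobic_yield`, optional salvage (boost) and conversion reactions, and a
#' single biomass drain.
#'
#' @param spec a `microbe_spec`.
#' @return a `metabolic_model` whose reactions carry the organism tag and
#'   subsystem annotations, with the metabolite mass vector attached.
#' @export
make_toy_microbe <- function(spec) {
  stopifnot(inherits(spec, "microbe_spec"))
  mass <- .toy_masses(spec)
  mets <- list()    # id -> compartment
  rxns <- list()    # each: list(id, stoich (named), lb, ub, subsystem)
  add_met <- function(id, comp) mets[[id]] <<- comp
  add_rxn <- function(id, stoich, lb, ub, subsystem) {
    rxns[[id]] <<- list(id = id, stoich = stoich, lb = lb, ub = ub,
                        subsystem = subsystem)
  }
  ex_of <- character(0)
  add_ex_pair <- function(m, transport_lb = 0, transport_ub = DEFAULT_BOUND,
                          sub = "transport") {
    # extracellular species + exchange; transporter e->c unless bounds say otherwise
    add_met(paste0(m, "_e"), "e")
    add_met(paste0(m, "_c"), "c")
    exid <- paste0("EX_", m)
    if (is.null(rxns[[exid]])) {
      add_rxn(exid, stats::setNames(-1, paste0(m, "_e")), 0, DEFAULT_BOUND, "exchange")
      ex_of <<- c(ex_of, exid)
    }
    tid <- paste0("T_", m)
    if (is.null(rxns[[tid]])) {
      add_rxn(tid, stats::setNames(c(-1, 1), paste0(m, c("_e", "_c"))),
              transport_lb, transport_ub, sub)
    }
  }
  add_met("P", "c")
  sugars <- setdiff(spec$carbon_sources, "fiber")
  if ("fiber" %in% spec$carbon_sources && !length(sugars)) sugars <- character(0)
  internal_sugars <- unique(c(sugars, if ("fiber" %in% spec$carbon_sources) "glc"))
  for (s in sugars) add_ex_pair(s, 0, spec$uptake_cap)
  if ("fiber" %in% spec$carbon_sources) {
    add_met("fiber_e", "e"); add_met("fiber_c", "c"); add_met("glc_c", "c")
    add_rxn("EX_fiber", c(fiber_e = -1), 0, DEFAULT_BOUND, "exchange")
    ex_of <- c(ex_of, "EX_fiber")
    add_rxn("T_fiber", c(fiber_e = -1, fiber_c = 1), 0, spec$uptake_cap, "transport")
    add_rxn("DEG_fiber", c(fiber_c = -1, glc_c = FIBER_LENGTH), 0, DEFAULT_BOUND,
            "degradation")
  }
  ferm_by <- names(spec$secretes)[spec$secretes == "ferment"]
  resp_by <- names(spec$secretes)[spec$secretes == "respire"]
  a <- spec$aerobic_yield; f <- spec$anaerobic_yield
  # a respiratory route only exists when it offers a distinct (higher) yield;
  # the oxygen coefficient is the mass-balancing degree of freedom
  has_resp <- a > f || length(resp_by) > 0
  s_o2 <- (a * mass[["P"]] + sum(mass[resp_by]) -
           f * mass[["P"]] - sum(mass[ferm_by])) / mass[["o2"]]
  if (has_resp && s_o2 <= 0) {
    stop("specification error: respiratory route cannot be mass-balanced; ",
         "increase aerobic_yield or lighten fermentation byproducts")
  }
  if (has_resp) add_ex_pair("o2", 0, DEFAULT_BOUND)
  for (s in internal_sugars) {
    sc <- paste0(s, "_c")
    st <- stats::setNames(c(-1, f), c(sc, "P"))
    for (b in ferm_by) st[paste0(b, "_c")] <- unname(st[paste0(b, "_c")] %||% 0) + 1
    add_rxn(paste0("FERM_", s), st, 0, DEFAULT_BOUND, "fermentation")
    if (has_resp) {
      st <- stats::setNames(c(-1, -s_o2, a), c(sc, "o2_c", "P"))
      for (b in resp_by) st[paste0(b, "_c")] <- unname(st[paste0(b, "_c")] %||% 0) + 1
      add_rxn(paste0("RESP_", s), st, 0, DEFAULT_BOUND, "respiration")
    }
  }
  for (b in names(spec$secretes)) {
    add_met(paste0(b, "_c"), "c")
    add_ex_pair(b)  # transporter allows re-import; secretion via reversible? keep export
    # byproduct leaves the cell: c -> e
    rxns[[paste0("T_", b)]]$stoich <- stats::setNames(c(-1, 1), paste0(b, c("_c", "_e")))
    rxns[[paste0("T_", b)]]$lb <- -DEFAULT_BOUND  # reversible: secrete or re-import
  }
  for (x in names(spec$boosts)) {
    add_ex_pair(x)
    add_rxn(paste0("SALV_", x),
            stats::setNames(c(-1, as.numeric(spec$boosts[[x]])), c(paste0(x, "_c"), "P")),
            0, DEFAULT_BOUND, "salvage")
  }
  for (cv in spec$converts) {
    from <- cv[["from"]]; to <- cv[["to"]]
    if (!from %in% spec$carbon_sources) {
      stop("specification error: conversion source '", from,
           "' is not a carbon source of ", spec$name)
    }
    ratio <- mass[[from]] / mass[[to]]
    add_met(paste0(to, "_c"), "c")
    add_rxn(paste0("CONV_", from, "_", to),
            stats::setNames(c(-1, ratio), paste0(c(from, to), "_c")),
            0, DEFAULT_BOUND, "conversion")
    add_ex_pair(to)
    rxns[[paste0("T_", to)]]$stoich <- stats::setNames(c(-1, 1), paste0(to, c("_c", "_e")))
    rxns[[paste0("T_", to)]]$lb <- -DEFAULT_BOUND
  }
  for (r in spec$requires) add_ex_pair(r)
  bio <- stats::setNames(-spec$biomass_p_cost, "P")
  for (r in spec$requires) bio[paste0(r, "_c")] <- -1
  add_rxn("BIOMASS", bio, 0, spec$max_growth, "biomass")

  met_ids <- names(mets)
  rxn_ids <- names(rxns)
  ti <- integer(0); tj <- integer(0); tx <- numeric(0)
  for (k in seq_along(rxns)) {
    r <- rxns[[k]]
    idx <- match(names(r$stoich), met_ids)
    if (anyNA(idx)) stop("specification error: undefined metabolite(s) ",
                         paste(names(r$stoich)[is.na(idx)], collapse = ", "))
    ti <- c(ti, idx); tj <- c(tj, rep(k, length(idx))); tx <- c(tx, unname(r$stoich))
  }
  S <- Matrix::sparseMatrix(i = ti, j = tj, x = tx,
                            dims = c(length(met_ids), length(rxn_ids)),
                            dimnames = list(met_ids, rxn_ids))
  base_of <- function(id) sub("_(e|c)$", "", id)
  masses <- stats::setNames(mass[base_of(met_ids)], met_ids)
  metabolites <- data.frame(id = met_ids,
                            compartment = unname(unlist(mets)),
                            name = met_ids, stringsAsFactors = FALSE)
  reactions <- data.frame(id = rxn_ids,
                          lb = vapply(rxns, function(r) r$lb, 0),
                          ub = vapply(rxns, function(r) r$ub, 0),
                          subsystem = vapply(rxns, function(r) r$subsystem, ""),
                          organism = spec$name, stringsAsFactors = FALSE,
                          row.names = NULL)
  metabolic_model(metabolites, reactions, S, biomass_ids = "BIOMASS",
                  exchange_ids = ex_of, masses = masses, name = spec$name)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Engineered cross-feeding pairs with known interaction motifs
#'
#' Returns a pair of toy microbes constructed so that the compartmentalized
#' pairwise protocol reproduces the requested interaction motif, together
#' with the diet under which the motif holds.  Recipes (all fermentative,
#' anaerobic two-sugar diet unless noted):
#' \describe{
#'   \item{neutralism}{disjoint substrates (glc vs fru), no byproducts.}
#'   \item{competition}{both organisms depend on the single shared glc cap.}
#'   \item{commensalism}{B ferments fru secreting `bx`; A salvages `bx` for
#'     extra growth; A gives nothing back.}
#'   \item{mutualism}{reciprocal version of commensalism (`bx` and `by`).}
#'   \item{amensalism}{shared glc; A is the high-yield consumer, B secretes a
#'     byproduct A can salvage, so total growth is allocation-invariant and
#'     the equitable co-culture optimum costs A its advantage while leaving B
#'     unchanged.}
#'   \item{parasitism}{B (inefficient biomass, private fru) can convert its
#'     substrate into `bx`, which A salvages at high yield; the co-culture
#'     optimum diverts all of B's carbon to A.}
#' }
#'
#' @param motif one of `"mutualism"`, `"commensalism"`, `"neutralism"`,
#'   `"amensalism"`, `"competition"`, `"parasitism"`.
#' @return list with elements `a`, `b` (metabolic models), `diet`
#'   (`diet_spec`) and `expected` (the motif).
#' @export
make_crossfeeding_pair <- function(motif = c("mutualism", "commensalism",
                                             "neutralism", "amensalism",
                                             "competition", "parasitism")) {
  motif <- match.arg(motif)
  diet <- make_diet("sugar", aerobic = FALSE)
  sp <- switch(motif,
    neutralism = list(
      microbe_spec("A", "glc", aerobic_yield = 1, anaerobic_yield = 1),
      microbe_spec("B", "fru", aerobic_yield = 1, anaerobic_yield = 1)),
    competition = list(
      microbe_spec("A", "glc", aerobic_yield = 1, anaerobic_yield = 1),
      microbe_spec("B", "glc", aerobic_yield = 1, anaerobic_yield = 1)),
    commensalism = list(
      microbe_spec("A", "glc", boosts = c(bx = 1),
                   aerobic_yield = 1, anaerobic_yield = 1),
      microbe_spec("B", "fru", secretes = c(bx = "ferment"),
                   aerobic_yield = 1, anaerobic_yield = 1,
                   mass_overrides = c(bx = 1))),
    mutualism = list(
      microbe_spec("A", "glc", secretes = c(by = "ferment"), boosts = c(bx = 1),
                   aerobic_yield = 1, anaerobic_yield = 1,
                   mass_overrides = c(by = 1)),
      microbe_spec("B", "fru", secretes = c(bx = "ferment"), boosts = c(by = 1),
                   aerobic_yield = 1, anaerobic_yield = 1,
                   mass_overrides = c(bx = 1))),
    amensalism = list(
      microbe_spec("A", "glc", boosts = c(bx = 1),
                   aerobic_yield = 2, anaerobic_yield = 2),
      microbe_spec("B", "glc", secretes = c(bx = "ferment"),
                   aerobic_yield = 1, anaerobic_yield = 1,
                   mass_overrides = c(bx = 1))),
    parasitism = list(
      microbe_spec("A", "glc", boosts = c(bx = 3),
                   aerobic_yield = 1, anaerobic_yield = 1),
      microbe_spec("B", "fru", converts = list(c(from = "fru", to = "bx")),
                   aerobic_yield = 1, anaerobic_yield = 1, biomass_p_cost = 2,
                   mass_overrides = c(bx = 3))))
  list(a = make_toy_microbe(sp[[1]]), b = make_toy_microbe(sp[[2]]),
       diet = diet, expected = motif)
}

#' Growth-capped cross-feeding pair for sampling envelopes
#'
#' A commensal-style pair (A secretes `bx`, B can salvage it) in which both
#' biomass reactions are capped at their mono-culture optimum (10 h^-1).
#' Cross-feeding is then invisible to FBA (the co-culture optimum equals the
#' sum of the mono-culture optima) but fully available to flux sampling,
#' which makes the pair the reference fixture for community growth-ratio
#' envelopes.
#'
#' @return list with `a`, `b`, `diet`.
#' @export
make_capped_crossfeeding_pair <- function() {
  a <- make_toy_microbe(microbe_spec("A", "glc", secretes = c(bx = "ferment"),
                                     aerobic_yield = 1, anaerobic_yield = 1,
                                     max_growth = 10, mass_overrides = c(bx = 1)))
  b <- make_toy_microbe(microbe_spec("B", "fru", boosts = c(bx = 1),
                                     aerobic_yield = 1, anaerobic_yield = 1,
                                     max_growth = 10))
  list(a = a, b = b, diet = make_diet("sugar", aerobic = FALSE))
}

#' Generate a synthetic community with random cross-feeding wiring
#'
#' Creates `n` toy microbes (all able to grow on glc, with deterministically
#' staggered yields) and wires directed byproduct->salvage edges between
#' ordered organism pairs with the given density, reproducibly for a given
#' seed.
#'
#' @param n number of organisms (>= 1).
#' @param crossfeed_density probability in `[0, 1]` of a cross-feeding edge
#'   for each ordered pair.
#' @param seed integer seed controlling the wiring.
#' @return list of `metabolic_model`s; the edge list is attached as the
#'   `"crossfeed_edges"` attribute (data.frame from, to, metabolite).
#' @export
make_community <- function(n, crossfeed_density = 0.3, seed = 1) {
  stopifnot(n >= 1, crossfeed_density >= 0, crossfeed_density <= 1)
  pairs <- if (n > 1) expand.grid(from = seq_len(n), to = seq_len(n)) else
    data.frame(from = integer(0), to = integer(0))
  pairs <- pairs[pairs$from != pairs$to, , drop = FALSE]
  draw <- local_seeded(seed, stats::runif(nrow(pairs)))
  edges <- pairs[draw < crossfeed_density, , drop = FALSE]
  edges$metabolite <- if (nrow(edges)) paste0("xf", edges$from, "_", edges$to) else character(0)
  specs <- lapply(seq_len(n), function(i) {
    sec <- edges$metabolite[edges$from == i]
    boo <- edges$metabolite[edges$to == i]
    microbe_spec(paste0("org", i), "glc",
                 secretes = if (length(sec)) stats::setNames(rep("ferment", length(sec)), sec),
                 boosts = if (length(boo)) stats::setNames(rep(0.25, length(boo)), boo),
                 aerobic_yield = 1 + 0.1 * (i - 1),
                 anaerobic_yield = 1 + 0.1 * (i - 1))
  })
  models <- lapply(specs, make_toy_microbe)
  attr(models, "crossfeed_edges") <- edges
  models
}

# Run expr under a fixed seed without disturbing the caller's RNG stream.
local_seeded <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Check mass consistency of a generated model
#'
#' For every non-exchange, non-biomass reaction, the declared metabolite mass
#' vector must be orthogonal to the reaction's stoichiometry.
#'
#' @param model a `metabolic_model` with masses attached.
#' @param tol numeric tolerance.
#' @return `TRUE` if consistent, otherwise the offending reaction ids.
#' @export
check_mass_consistency <- function(model, tol = 1e-8) {
  model <- as_metabolic_model(model)
  if (is.null(model$masses)) stop("model carries no metabolite mass vector")
  skip <- union(model$biomass_ids, model$exchange_ids)
  j <- setdiff(model$reactions$id, skip)
  resid <- abs(as.numeric(model$masses %*% model$stoich[, j, drop = FALSE]))
  if (all(resid <= tol)) TRUE else j[resid > tol]
}

#' Engineered pairs for the costless-secretion loop
#'
#' Fixtures with hand-traceable costless dynamics on a single supplied
#' carbon source:
#' \describe{
#'   \item{commensal}{A ferments glc and secretes acetate (`ac`); B can only
#'     grow on `ac`.  B is rescued from zero growth once acetate enters the
#'     media; expected label `"C1a"`.}
#'   \item{mutualistic}{A ferments glc secreting `ac` and salvages `vit`; B
#'     grows on `ac` secreting `vit`.  Reciprocal exchange; expected label
#'     `"M1a"`.}
#'   \item{independent}{A grows on the supplied glc, B on the fru present in
#'     the minimal media; no secretions feed anyone; expected label
#'     `"N1a"`.}
#' }
#'
#' @param type fixture kind.
#' @return list with `models`, `media` (named caps), `carbon_sources`,
#'   `expected_label`.
#' @export
make_costless_pair <- function(type = c("commensal", "mutualistic", "independent")) {
  type <- match.arg(type)
  switch(type,
    commensal = list(
      models = list(
        make_toy_microbe(microbe_spec("A", "glc", secretes = c(ac = "ferment"),
                                      aerobic_yield = 1, anaerobic_yield = 1,
                                      mass_overrides = c(ac = 1))),
        make_toy_microbe(microbe_spec("B", "ac", aerobic_yield = 1,
                                      anaerobic_yield = 1,
                                      mass_overrides = c(ac = 1)))),
      media = numeric(0), carbon_sources = "glc", expected_label = "C1a"),
    mutualistic = list(
      models = list(
        make_toy_microbe(microbe_spec("A", "glc", secretes = c(ac = "ferment"),
                                      boosts = c(vit = 0.5),
                                      aerobic_yield = 1, anaerobic_yield = 1,
                                      mass_overrides = c(ac = 1.5))),
        make_toy_microbe(microbe_spec("B", "ac", secretes = c(vit = "ferment"),
                                      aerobic_yield = 1, anaerobic_yield = 1,
                                      mass_overrides = c(ac = 1.5, vit = 0.5)))),
      media = numeric(0), carbon_sources = "glc", expected_label = "M1a"),
    independent = list(
      models = list(
        make_toy_microbe(microbe_spec("A", "glc", aerobic_yield = 1,
                                      anaerobic_yield = 1)),
        make_toy_microbe(microbe_spec("B", "fru", aerobic_yield = 1,
                                      anaerobic_yield = 1))),
      media = c(fru = 10), carbon_sources = "glc", expected_label = "N1a"))
}
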