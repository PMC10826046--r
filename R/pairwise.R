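# The pairwise interaction protocol: join two organisms through a lumen,
# constrain to a diet, simulate mono-cultures by shutting one organism off,
# simulate co-culture, and classify the growth changes into one of six
# ecological motifs against a relative threshold (default 10%).

INTERACTION_TYPES <- c("mutualism", "commensalism", "neutralism",
                       "amensalism", "parasitism", "competition")

# fixed order used to break ties when picking modal calls
TYPE_TIE_ORDER <- c("mutualism", "commensalism", "neutralism",
                    "amensalism", "parasitism", "competition")

.growth_label <- function(mono, co, delta, eps_zero) {
  if (mono <= eps_zero) {
    if (co > eps_zero) "faster" else "unchanged"
  } else if (co > (1 + delta) * mono) {
    "faster"
  } else if (co < (1 - delta) * mono) {
    "slower"
  } else "unchanged"
}

.label_pair_type <- function(la, lb) {
  key <- paste(sort(c(la, lb)), collapse = "/")
  switch(key,
         "faster/faster" = "mutualism",
         "slower/slower" = "competition",
         "unchanged/unchanged" = "neutralism",
         "faster/unchanged" = "commensalism",
         "slower/unchanged" = "amensalism",
         "faster/slower" = "parasitism")
}

#' Classify a pairwise interaction from four growth rates
#'
#' Labels each organism faster (co-culture growth above `(1+delta)` times its
#' mono-culture growth), slower (below `(1-delta)` times), or unchanged, and
#' maps the label pair to one of the six motifs: both faster = mutualism,
#' both slower = competition, both unchanged = neutralism, faster/unchanged =
#' commensalism, slower/unchanged = amensalism, faster/slower = parasitism.
#' When a mono-culture growth is zero the relative rule is undefined; the
#' organism counts as faster only if its co-culture growth exceeds an
#' absolute floor `eps_zero`.
#'
#' @param g_a_mono,g_b_mono,g_a_co,g_b_co nonnegative growth rates (h^-1).
#' @param delta relative-change threshold in (0, 1); default 0.10.
#' @param eps_zero absolute growth floor used for zero mono-culture growth.
#' @return an `interaction_call`: list with `type`, the four growths, the
#'   per-organism labels and `orientation` (which organism benefits/suffers
#'   for the asymmetric types).
#' @export
classify_interaction <- function(g_a_mono, g_b_mono, g_a_co, g_b_co,
                                 delta = 0.10, eps_zero = 1e-6) {
  if (any(c(g_a_mono, g_b_mono, g_a_co, g_b_co) < 0)) {
    stop("growth rates must be nonnegative")
  }
  stopifnot(delta > 0, delta < 1)
  la <- .growth_label(g_a_mono, g_a_co, delta, eps_zero)
  lb <- .growth_label(g_b_mono, g_b_co, delta, eps_zero)
  type <- .label_pair_type(la, lb)
  orientation <- if (la == lb) NA_character_
    else if (type == "parasitism") { if (la == "faster") "a_benefits" else "b_benefits" }
    else if (type == "commensalism") { if (la == "faster") "a_benefits" else "b_benefits" }
    else if (type == "amensalism") { if (la == "slower") "a_suffers" else "b_suffers" }
  structure(list(type = type, growth_a_mono = g_a_mono, growth_b_mono = g_b_mono,
                 growth_a_co = g_a_co, growth_b_co = g_b_co,
                 label_a = la, label_b = lb, threshold = delta,
                 orientation = orientation),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat("<interaction_call> ", x$type,
      sprintf("  [A: %.4g -> %.4g (%s); B: %.4g -> %.4g (%s)]",
              x$growth_a_mono, x$growth_a_co, x$label_a,
              x$growth_b_mono, x$growth_b_co, x$label_b), "\n", sep = "")
  invisible(x)
}

# Steps 1-5 shared by both protocol modes: join, diet, mono-culture FBA.
.pairwise_setup <- function(model_a, model_b, diet) {
  comm <- apply_diet(join_compartmentalized(model_a, model_b), diet)
  tags <- comm$organisms
  bio <- comm$model$biomass_ids
  mono_a <- solve_fba(shut_off(comm, tags[2]), bio[1])$objective_value
  mono_b <- solve_fba(shut_off(comm, tags[1]), bio[2])$objective_value
  list(comm = comm, tags = tags, bio = bio, mono_a = mono_a, mono_b = mono_b)
}

# Co-culture growth under the joint reading: maximize the summed growth, then
# resolve degeneracy deterministically by maximizing the smaller of the two
# growths at the fixed optimal sum (the equitable point of the optimal face).
.co_growth_joint <- function(comm, bio) {
  mm <- comm$model
  rxn <- mm$reactions
  n <- nrow(rxn)
  ja <- match(bio[1], rxn$id); jb <- match(bio[2], rxn$id)
  obj <- numeric(n); obj[c(ja, jb)] <- 1
  S <- as.matrix(mm$stoich)
  b0 <- rep(0, nrow(S))
  first <- lp_solve(obj, A_eq = S, b_eq = b0, lb = rxn$lb, ub = rxn$ub)
  if (first$status != "optimal") stop("co-culture FBA failed: ", first$status)
  s_star <- first$objective
  # second stage: variables (v, t); maximize t s.t. t <= g_a, t <= g_b,
  # g_a + g_b = s_star
  obj2 <- c(numeric(n), 1)
  A_eq2 <- rbind(cbind(S, 0), c(obj, 0))
  b_eq2 <- c(b0, s_star)
  A_le <- matrix(0, 2, n + 1)
  A_le[1, ja] <- -1; A_le[1, n + 1] <- 1
  A_le[2, jb] <- -1; A_le[2, n + 1] <- 1
  res <- lp_solve(obj2, A_eq = A_eq2, b_eq = b_eq2,
                  A_le = A_le, b_le = c(0, 0),
                  lb = c(rxn$lb, -Inf), ub = c(rxn$ub, Inf))
  if (res$status != "optimal") stop("co-culture tie-break LP failed: ", res$status)
  c(res$x[ja], res$x[jb])
}

.co_growth_separate <- function(comm, bio) {
  c(solve_fba(comm, bio[1])$objective_value,
    solve_fba(comm, bio[2])$objective_value)
}

#' Pairwise interaction protocol, FBA mode
#'
#' Runs the full compartmentalized protocol with FBA: join through a lumen,
#' apply the diet, compute each organism's mono-culture optimum with the
#' partner shut off, compute the co-culture growths, and classify.
#'
#' Two co-culture readings are available.  `"joint"` (default) maximizes the
#' summed community growth and resolves degeneracy at the optimal face by
#' maximizing the smaller growth; this coupling lets resource conflict
#' register as reduced growth.  `"separate"` maximizes each organism's
#' biomass in its own LP; because the partner's network can only add routes,
#' growth reductions are invisible in this reading (see the methods
#' vignette).
#'
#' @param model_a,model_b `metabolic_model`s.
#' @param diet a `diet_spec` or named cap vector.
#' @param delta classification threshold.
#' @param co_mode `"joint"` or `"separate"`.
#' @param settings [fba_settings()].
#' @return an `interaction_call` with the community model attached as
#'   attribute `"community"` and the co-culture FBA sum as `"fba_co_sum"`.
#' @export
pairwise_protocol_fba <- function(model_a, model_b, diet, delta = 0.10,
                                  co_mode = c("joint", "separate"),
                                  settings = fba_settings()) {
  co_mode <- match.arg(co_mode)
  setup <- .pairwise_setup(model_a, model_b, diet)
  g_co <- if (co_mode == "joint") .co_growth_joint(setup$comm, setup$bio)
          else .co_growth_separate(setup$comm, setup$bio)
  call <- classify_interaction(setup$mono_a, setup$mono_b, g_co[1], g_co[2],
                               delta = delta)
  attr(call, "community") <- setup$comm
  attr(call, "fba_co_sum") <- sum(g_co)
  call
}

#' Pairwise interaction protocol, sampling mode
#'
#' Replaces the FBA optimizations of the protocol's simulation steps with
#' uniform flux sampling.  Mono-cultures are sampled with the partner shut
#' off; the co-culture is sampled with both organisms active.  In every
#' sampled condition each organism's biomass is bounded below by
#' `basal_fraction` times its mono-culture FBA optimum, excluding zero-growth
#' states.  Each co-culture sample is classified against a mono-culture
#' reference growth; with the default `reference = "quantile"` the reference
#' is the mono-culture growth at the same quantile as the sample's rank, so
#' that a co-culture distribution identical to mono-culture reads as
#' unchanged. `"median"` compares against the mono-culture sampled median and
#' `"fba"` against the mono-culture FBA optimum.
#'
#' @inheritParams pairwise_protocol_fba
#' @param sampler_settings a [sampler_settings()] object.
#' @param basal_fraction basal growth fraction (default 0.1).
#' @param reference reference growth for per-sample classification.
#' @return list of class `pairwise_sampling_result` with mono and co-culture
#'   `flux_sample_set`s, the per-sample `calls` data.frame, the call
#'   `distribution` (per-sample type frequencies), `modal_call`, the four
#'   FBA growths and the co-culture FBA sum.
#' @export
pairwise_protocol_sampling <- function(model_a, model_b, diet,
                                       sampler_settings = NULL,
                                       basal_fraction = 0.1, delta = 0.10,
                                       reference = c("quantile", "median", "fba")) {
  reference <- match.arg(reference)
  if (is.null(sampler_settings)) sampler_settings <- sampler_settings()
  setup <- .pairwise_setup(model_a, model_b, diet)
  comm <- setup$comm; tags <- setup$tags; bio <- setup$bio
  if (setup$mono_a <= 0 && setup$mono_b <= 0) {
    stop("neither organism grows in mono-culture under this diet")
  }
  basal <- c(setup$mono_a, setup$mono_b) * basal_fraction
  set_lb <- function(cm, id, v) {
    j <- match(id, cm$model$reactions$id)
    cm$model$reactions$lb[j] <- v
    cm
  }
  mono_a_model <- set_lb(shut_off(comm, tags[2]), bio[1], basal[1])
  mono_b_model <- set_lb(shut_off(comm, tags[1]), bio[2], basal[2])
  co_model <- set_lb(set_lb(comm, bio[1], basal[1]), bio[2], basal[2])
  reseed <- function(s, k) { s$seed <- s$seed + k; s }
  ss_a <- sample_fluxes(mono_a_model, reseed(sampler_settings, 1L))
  ss_b <- sample_fluxes(mono_b_model, reseed(sampler_settings, 2L))
  ss_co <- tryCatch(sample_fluxes(co_model, reseed(sampler_settings, 3L)),
                    error = function(e) e)
  if (inherits(ss_co, "error")) {
    out <- list(feasible = FALSE, message = conditionMessage(ss_co),
                mono_a = ss_a, mono_b = ss_b)
    class(out) <- "pairwise_sampling_result"
    return(out)
  }
  g_a_mono <- ss_a$samples[, bio[1]]
  g_b_mono <- ss_b$samples[, bio[2]]
  g_a_co <- ss_co$samples[, bio[1]]
  g_b_co <- ss_co$samples[, bio[2]]
  n <- length(g_a_co)
  ref_for <- function(co, mono, mono_fba) {
    switch(reference,
           quantile = stats::quantile(mono, probs = (rank(co, ties.method = "first") - 0.5) / n,
                                      names = FALSE, type = 7),
           median = rep(stats::median(mono), n),
           fba = rep(mono_fba, n))
  }
  ref_a <- ref_for(g_a_co, g_a_mono, setup$mono_a)
  ref_b <- ref_for(g_b_co, g_b_mono, setup$mono_b)
  types <- character(n)
  for (i in seq_len(n)) {
    la <- .growth_label(ref_a[i], g_a_co[i], delta, 1e-6)
    lb <- .growth_label(ref_b[i], g_b_co[i], delta, 1e-6)
    types[i] <- .label_pair_type(la, lb)
  }
  calls <- data.frame(g_a = g_a_co, g_b = g_b_co, ref_a = ref_a, ref_b = ref_b,
                      type = types, stringsAsFactors = FALSE)
  dist <- table(factor(types, levels = INTERACTION_TYPES)) / n
  modal <- .modal_type(types)
  g_co_fba <- .co_growth_joint(comm, bio)
  out <- list(feasible = TRUE, mono_a = ss_a, mono_b = ss_b, co = ss_co,
              calls = calls, distribution = dist, modal_call = modal,
              growth_a_mono_fba = setup$mono_a, growth_b_mono_fba = setup$mono_b,
              fba_co = g_co_fba, fba_co_sum = sum(g_co_fba),
              biomass_ids = bio, organisms = tags,
              basal_fraction = basal_fraction, delta = delta,
              reference = reference)
  class(out) <- "pairwise_sampling_result"
  out
}

.modal_type <- function(types) {
  counts <- table(factor(types, levels = TYPE_TIE_ORDER))
  names(counts)[which.max(counts)]  # which.max takes the first max: tie order
}

#' @export
print.pairwise_sampling_result <- function(x, ...) {
  if (!isTRUE(x$feasible)) {
    cat("<pairwise_sampling_result> infeasible pair:", x$message, "\n")
    return(invisible(x))
  }
  cat("<pairwise_sampling_result> modal call:", x$modal_call, "\n")
  print(round(x$distribution, 3))
  invisible(x)
}

#' Regime map over sampled co-culture growth rates
#'
#' Bins the two organisms' co-culture growth rates into quantile bins and
#' reports the modal per-sample interaction call in every cell, phase-diagram
#' style.  Quantile binning keeps cell support comparable; ties in the modal
#' call are broken by a fixed type order for determinism.
#'
#' @param result a `pairwise_sampling_result`, or a data.frame with columns
#'   `g_a`, `g_b`, `type`.
#' @param n_bins number of bins per organism (>= 1).
#' @return data.frame of class `regime_map` with columns `bin_a`, `bin_b`,
#'   bin interval midpoints, modal `type` (NA for empty cells) and `support`.
#' @export
build_regime_map <- function(result, n_bins = 20) {
  if (n_bins < 1) stop("n_bins must be >= 1")
  calls <- if (inherits(result, "pairwise_sampling_result")) result$calls else result
  stopifnot(nrow(calls) > 0)
  qbreaks <- function(g) {
    br <- unique(stats::quantile(g, probs = seq(0, 1, length.out = n_bins + 1)))
    if (length(br) < 2) br <- c(br, br + 1e-12)
    br
  }
  br_a <- qbreaks(calls$g_a); br_b <- qbreaks(calls$g_b)
  ia <- cut(calls$g_a, br_a, include.lowest = TRUE, labels = FALSE)
  ib <- cut(calls$g_b, br_b, include.lowest = TRUE, labels = FALSE)
  grid <- expand.grid(bin_a = seq_len(length(br_a) - 1),
                      bin_b = seq_len(length(br_b) - 1))
  grid$mid_a <- (br_a[grid$bin_a] + br_a[grid$bin_a + 1]) / 2
  grid$mid_b <- (br_b[grid$bin_b] + br_b[grid$bin_b + 1]) / 2
  grid$type <- NA_character_
  grid$support <- 0L
  for (k in seq_len(nrow(grid))) {
    sel <- which(ia == grid$bin_a[k] & ib == grid$bin_b[k])
    grid$support[k] <- length(sel)
    if (length(sel)) grid$type[k] <- .modal_type(calls$type[sel])
  }
  class(grid) <- c("regime_map", class(grid))
  grid
}

#' Community growth ratio of sampled versus FBA co-culture growth
#'
#' Per co-culture sample, `100 * (g_a + g_b) / (g_a + g_b)_FBA`: the summed
#' sampled growth as a percentage of the pair's summed FBA co-culture growth.
#'
#' @param result a `pairwise_sampling_result`.
#' @param fba_co_sum optional override for the FBA denominator.
#' @return numeric vector of percentages (NA when the denominator is zero).
#' @export
community_growth_ratio <- function(result, fba_co_sum = NULL) {
  stopifnot(inherits(result, "pairwise_sampling_result"), isTRUE(result$feasible))
  denom <- if (is.null(fba_co_sum)) result$fba_co_sum else fba_co_sum
  if (!isTRUE(denom > 0)) return(rep(NA_real_, nrow(result$calls)))
  100 * (result$calls$g_a + result$calls$g_b) / denom
}

#' Interaction-type frequency table
#'
#' Percentages of each interaction type, optionally per condition, plus the
#' derived aggregates used when comparing methods: antagonistic (competition
#' + amensalism + parasitism), cooperative or net-neutral (commensalism +
#' neutralism + mutualism) and symmetrical (mutualism + neutralism +
#' competition).
#'
#' @param calls a character vector of types, a list of `interaction_call`s,
#'   or a data.frame with a `type` column and optional grouping columns.
#' @param grouping character vector of grouping column names (data.frame
#'   input only).
#' @return data.frame with one row per (condition,) type and columns
#'   `percent`, plus an `aggregates` attribute.
#' @export
summarize_interaction_frequencies <- function(calls, grouping = NULL) {
  if (is.list(calls) && length(calls) && inherits(calls[[1]], "interaction_call")) {
    calls <- data.frame(type = vapply(calls, `[[`, "", "type"), stringsAsFactors = FALSE)
  } else if (is.character(calls)) {
    calls <- data.frame(type = calls, stringsAsFactors = FALSE)
  }
  stopifnot(nrow(calls) > 0)
  split_by <- if (length(grouping)) interaction(calls[grouping], drop = TRUE)
              else factor(rep("all", nrow(calls)))
  out <- do.call(rbind, lapply(levels(split_by), function(g) {
    sub <- calls$type[split_by == g]
    tab <- table(factor(sub, levels = INTERACTION_TYPES))
    data.frame(condition = g, type = names(tab),
               percent = 100 * as.numeric(tab) / length(sub),
               stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(out, out$condition), function(d) {
    pct <- stats::setNames(d$percent, d$type)
    data.frame(condition = d$condition[1],
               antagonistic = sum(pct[c("competition", "amensalism", "parasitism")]),
               cooperative = sum(pct[c("commensalism", "neutralism", "mutualism")]),
               symmetrical = sum(pct[c("mutualism", "neutralism", "competition")]),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  attr(out, "aggregates") <- agg
  out
}

#' Enumerate unique unordered model pairs
#'
#' @param models an integer (number of models) or a list/vector of model
#'   identifiers.
#' @return data.frame with columns `a`, `b`, one row per unique pair.
#' @export
pair_design <- function(models) {
  ids <- if (is.numeric(models) && length(models) == 1) seq_len(models)
         else if (is.list(models)) vapply(models, function(m) as_metabolic_model(m)$name, "")
         else models
  if (length(ids) < 2) return(data.frame(a = ids[0], b = ids[0]))
  cmb <- utils::combn(ids, 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], stringsAsFactors = FALSE)
}
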