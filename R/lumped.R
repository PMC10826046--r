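# Analytics for the lumped (pooled) community model: per-species biomass
# optimization, the max-min optimal community growth, pathway-level flux
# summaries, per-reaction divergence between flux distributions, and
# metabolite flux-sum turnover.

#' Iteratively optimize each organism's biomass in a pooled model
#'
#' Sets each biomass reaction in turn as the FBA objective (all other
#' organisms unconstrained) and records the solution.  Infeasibility for one
#' organism is recorded as `NULL`, not raised.
#'
#' @param pooled a `community_model` from [pool_models()] (or any model with
#'   several biomass reactions).
#' @return named list, organism biomass id -> `flux_vector` (or `NULL`).
#' @export
iterative_biomass_optimization <- function(pooled) {
  mm <- as_metabolic_model(pooled)
  out <- stats::setNames(vector("list", length(mm$biomass_ids)), mm$biomass_ids)
  for (b in mm$biomass_ids) {
    out[[b]] <- tryCatch(solve_fba(mm, b), error = function(e) NULL)
  }
  out
}

#' Optimal community growth of a pooled model
#'
#' The largest growth rate `g*` that every organism can achieve
#' simultaneously: `max g` subject to steady state, bounds, and
#' `v_biomass_k >= g` for every organism `k` (one LP with an auxiliary
#' variable).  The returned constrained model has every biomass lower bound
#' raised to `g*`.
#'
#' @param pooled a `community_model` with one biomass reaction per organism.
#' @return list of class `optimal_community_result` with `g_star` and
#'   `constrained_model`.
#' @export
optimal_community_growth <- function(pooled) {
  mm <- as_metabolic_model(pooled)
  rxn <- mm$reactions
  n <- nrow(rxn)
  bidx <- match(mm$biomass_ids, rxn$id)
  S <- as.matrix(mm$stoich)
  A_le <- matrix(0, length(bidx), n + 1)
  for (k in seq_along(bidx)) {
    A_le[k, bidx[k]] <- -1
    A_le[k, n + 1] <- 1            # g - v_bio_k <= 0
  }
  res <- lp_solve(c(numeric(n), 1), A_eq = cbind(S, 0), b_eq = rep(0, nrow(S)),
                  A_le = A_le, b_le = numeric(length(bidx)),
                  lb = c(rxn$lb, 0), ub = c(rxn$ub, Inf), maximize = TRUE)
  if (res$status != "optimal") {
    stop("optimal community growth LP failed: ", res$status)
  }
  g_star <- res$objective
  constrained <- pooled
  cm <- as_metabolic_model(constrained)
  cm$reactions$lb[bidx] <- pmax(cm$reactions$lb[bidx], g_star)
  if (inherits(constrained, "community_model")) constrained$model <- cm else constrained <- cm
  structure(list(g_star = g_star, constrained_model = constrained),
            class = "optimal_community_result")
}

#' @export
print.optimal_community_result <- function(x, ...) {
  cat("<optimal_community_result> g* =", format(x$g_star), "\n")
  invisible(x)
}

# |flux| matrix (rows = observations) from a sample set, a flux_vector, or a
# list of flux_vectors.
.abs_flux_matrix <- function(x) {
  if (inherits(x, "flux_sample_set")) return(abs(x$samples))
  if (inherits(x, "flux_vector")) x <- list(x)
  if (is.list(x)) {
    x <- Filter(Negate(is.null), x)
    stopifnot(length(x) > 0)
    return(abs(do.call(rbind, lapply(x, function(fv) fv$values))))
  }
  abs(as.matrix(x))
}

#' Median normalized pathway flux, sampling versus optimization
#'
#' For each reaction, |flux| is normalized by the maximum |flux| the reaction
#' attains across both compared conditions; medians are then taken within
#' each subsystem across all reactions and observations.  The output pairs
#' the two methods per subsystem, the form behind sampling-vs-FBA pathway
#' scatter plots.
#'
#' @param sampling a `flux_sample_set` (or flux matrix).
#' @param optimization a `flux_vector`, list of flux vectors (e.g. the
#'   per-organism optimizations), or flux matrix.
#' @param model the model supplying subsystem annotations; reactions without
#'   one are grouped as `"unassigned"`.
#' @return data.frame with columns `subsystem`, `median_sampling`,
#'   `median_optimization`, `n_reactions`.
#' @export
pathway_flux_summary <- function(sampling, optimization, model) {
  mm <- as_metabolic_model(model)
  P <- .abs_flux_matrix(sampling)
  Q <- .abs_flux_matrix(optimization)
  ids <- mm$reactions$id
  stopifnot(all(ids %in% colnames(P)), all(ids %in% colnames(Q)))
  P <- P[, ids, drop = FALSE]; Q <- Q[, ids, drop = FALSE]
  fmax <- pmax(apply(P, 2, max), apply(Q, 2, max))
  fmax[fmax < 1e-12] <- 1   # all-zero reactions stay zero after normalization
  Pn <- sweep(P, 2, fmax, "/")
  Qn <- sweep(Q, 2, fmax, "/")
  sub <- mm$reactions$subsystem
  sub[is.na(sub) | sub == ""] <- "unassigned"
  out <- do.call(rbind, lapply(sort(unique(sub)), function(s) {
    j <- which(sub == s)
    data.frame(subsystem = s,
               median_sampling = stats::median(Pn[, j]),
               median_optimization = stats::median(Qn[, j]),
               n_reactions = length(j), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Histogram KL divergence on shared equal-width bins with additive
# pseudocounts; natural log.
.kl_pair <- function(p, q, bins, pseudocount) {
  rng <- range(c(p, q))
  if (diff(rng) <= 0) return(c(0, 0))
  br <- seq(rng[1], rng[2], length.out = bins + 1)
  cp <- graphics::hist(p, breaks = br, plot = FALSE)$counts + pseudocount
  cq <- graphics::hist(q, breaks = br, plot = FALSE)$counts + pseudocount
  P <- cp / sum(cp); Q <- cq / sum(cq)
  c(sum(P * log(P / Q)), sum(Q * log(Q / P)))
}

#' Bidirectional KL divergence between per-reaction flux distributions
#'
#' Histogram-based estimates of `D(P||Q)` and `D(Q||P)` per reaction on
#' shared equal-width bins with additive pseudocounts, their sum, the median
#' flux difference, and a low/medium/high class from configurable cutoffs on
#' the summed divergence.  Degenerate (zero-spread) pairs compare as point
#' masses and score zero divergence.
#'
#' @param P a `flux_sample_set` or flux matrix (observations x reactions).
#' @param Q a second sample set, flux matrix, `flux_vector` or list of flux
#'   vectors covering the same reactions.
#' @param bins number of shared histogram bins (default 30).
#' @param pseudocount additive count per bin (default 1).
#' @param cutoffs numeric `c(low, high)`: `kl_sum < low` is "low",
#'   `kl_sum > high` is "high", otherwise "medium".
#' @return data.frame with columns `reaction`, `kl_forward`, `kl_backward`,
#'   `kl_sum`, `median_difference`, `class`.
#' @export
reaction_divergence <- function(P, Q, bins = 30, pseudocount = 1,
                                cutoffs = c(low = 0.05, high = 1.0)) {
  Pm <- if (inherits(P, "flux_sample_set")) P$samples else as.matrix(P)
  Qm <- if (inherits(Q, "flux_sample_set")) Q$samples else {
    if (inherits(Q, "flux_vector") || (is.list(Q) && !is.matrix(Q)))
      do.call(rbind, lapply(if (inherits(Q, "flux_vector")) list(Q) else
        Filter(Negate(is.null), Q), function(fv) fv$values))
    else as.matrix(Q)
  }
  common <- intersect(colnames(Pm), colnames(Qm))
  if (!length(common)) stop("P and Q share no reactions")
  out <- data.frame(reaction = common, kl_forward = NA_real_,
                    kl_backward = NA_real_, kl_sum = NA_real_,
                    median_difference = NA_real_, class = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(common)) {
    p <- Pm[, common[i]]; q <- Qm[, common[i]]
    kl <- .kl_pair(p, q, bins, pseudocount)
    out$kl_forward[i] <- kl[1]
    out$kl_backward[i] <- kl[2]
    out$kl_sum[i] <- sum(kl)
    out$median_difference[i] <- stats::median(p) - stats::median(q)
  }
  out$class <- ifelse(out$kl_sum < cutoffs[["low"]], "low",
                      ifelse(out$kl_sum > cutoffs[["high"]], "high", "medium"))
  out
}

#' Metabolite flux-sum turnover
#'
#' The flux-sum of metabolite i is half the total absolute flux it
#' participates in, `Phi_i = 0.5 * sum_j |S_ij v_j|`: at steady state, its
#' turnover rate.  Computed per sample; the per-metabolite median is
#' reported.
#'
#' @param sample_set a `flux_sample_set`, flux matrix, `flux_vector` or list
#'   of flux vectors.
#' @param model the source model (supplies S).
#' @return data.frame with columns `metabolite`, `median_flux_sum`; the full
#'   per-sample matrix (samples x metabolites) is attached as attribute
#'   `"phi"`.
#' @export
flux_sum <- function(sample_set, model) {
  mm <- as_metabolic_model(model)
  V <- if (inherits(sample_set, "flux_sample_set")) sample_set$samples
       else if (inherits(sample_set, "flux_vector")) t(sample_set$values)
       else if (is.list(sample_set) && !is.matrix(sample_set))
         do.call(rbind, lapply(Filter(Negate(is.null), sample_set),
                               function(fv) fv$values))
       else as.matrix(sample_set)
  V <- V[, mm$reactions$id, drop = FALSE]
  absS <- abs(as.matrix(mm$stoich))
  phi <- 0.5 * abs(V) %*% t(absS)   # samples x metabolites
  colnames(phi) <- mm$metabolites$id
  out <- data.frame(metabolite = mm$metabolites$id,
                    median_flux_sum = apply(phi, 2, stats::median),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "phi") <- phi
  out
}
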