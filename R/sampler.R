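# Uniform sampling of the steady-state flux polytope
# {v : S v = 0, lb <= v <= ub} by artificial-centering hit-and-run over a
# null-space parameterization: the equality constraints are eliminated once
# (v = v0 + N alpha with N an orthonormal null-space basis of S), so every
# chain position satisfies steady state exactly and only the box constraints
# bound each line search.

#' Sampler settings
#'
#' @param n_samples number of samples to return (>= 1).
#' @param steps_per_point thinning interval: chain steps between recorded
#'   samples (>= 1).
#' @param seed integer seed; identical settings and model give bit-identical
#'   sample sets.
#' @param warmup number of discarded initial steps; default
#'   `max(1000, 10 * polytope dimension)`.
#' @param steady_state_tolerance feasibility tolerance used when validating
#'   emitted samples.
#' @return a list of class `sampler_settings`.
#' @export
sampler_settings <- function(n_samples = 1000, steps_per_point = 200,
                             seed = 1, warmup = NULL,
                             steady_state_tolerance = 1e-9) {
  stopifnot(n_samples >= 1, steps_per_point >= 1)
  structure(list(n_samples = as.integer(n_samples),
                 steps_per_point = as.integer(steps_per_point),
                 seed = as.integer(seed), warmup = warmup,
                 steady_state_tolerance = steady_state_tolerance),
            class = "sampler_settings")
}

# Orthonormal null-space basis of S with a relative singular-value tolerance.
.null_space <- function(S, rel_tol = 1e-10) {
  S <- as.matrix(S)
  if (nrow(S) == 0) return(diag(ncol(S)))
  sv <- svd(S, nu = 0, nv = ncol(S))
  keep <- sv$d > rel_tol * max(sv$d, 1)
  rank <- sum(keep)
  if (rank == ncol(S)) matrix(0, ncol(S), 0) else sv$v[, (rank + 1):ncol(S), drop = FALSE]
}

# Interior starting point: maximize the uniform margin t to all non-fixed
# bounds (a Chebyshev-center-like LP in the box metric).
.interior_point <- function(S, lb, ub) {
  n <- length(lb)
  hw <- (ub - lb) / 2
  act <- which(hw > 1e-12)
  t_cap <- if (length(act)) min(hw[act]) else 0
  A_le <- NULL; b_le <- NULL
  rows <- list(); rhs <- numeric(0)
  for (j in act) {
    r1 <- numeric(n + 1); r1[j] <- -1; r1[n + 1] <- 1   # lb_j + t <= v_j
    r2 <- numeric(n + 1); r2[j] <- 1; r2[n + 1] <- 1    # v_j + t <= ub_j
    rows[[length(rows) + 1]] <- r1; rhs <- c(rhs, -lb[j])
    rows[[length(rows) + 1]] <- r2; rhs <- c(rhs, ub[j])
  }
  A_le <- do.call(rbind, rows)
  obj <- c(numeric(n), 1)
  res <- lp_solve(obj, A_eq = cbind(S, 0), b_eq = rep(0, nrow(S)),
                  A_le = A_le, b_le = rhs,
                  lb = c(lb, 0), ub = c(ub, t_cap), maximize = TRUE)
  if (res$status != "optimal") return(NULL)
  res$x[seq_len(n)]
}

#' Sample the steady-state flux polytope
#'
#' Draws approximately uniform flux samples by artificial-centering
#' hit-and-run: after a warmup of random-direction hit-and-run steps from an
#' interior start, chain directions are drawn through the running center and
#' a randomly chosen stored point, and the chain is thinned by
#' `steps_per_point`.  All emitted rows satisfy the bounds and
#' `|S v| <= tolerance` (asserted before returning).
#'
#' @param model a `metabolic_model` or `community_model`; all reaction bounds
#'   must be finite (cap exchanges before sampling).
#' @param settings a [sampler_settings()] object.
#' @return a `flux_sample_set`: list with `samples` (n_samples x n_reactions
#'   matrix, columns named by reaction id) and `provenance`.
#' @export
sample_fluxes <- function(model, settings = sampler_settings()) {
  mm <- as_metabolic_model(model)
  rxn <- mm$reactions
  lb <- rxn$lb; ub <- rxn$ub
  if (any(!is.finite(lb)) || any(!is.finite(ub))) {
    stop("polytope has unbounded directions; cap the exchange bounds before sampling")
  }
  S <- as.matrix(mm$stoich)
  v0_full <- .interior_point(S, lb, ub)
  if (is.null(v0_full)) stop("flux polytope is empty (infeasible constraints)")
  n_full <- length(lb)
  tol <- settings$steady_state_tolerance
  n_samples <- settings$n_samples
  # variables pinned by their bounds (e.g. a shut-off organism) are constants:
  # eliminate them before the null-space construction so the chain only
  # proposes directions the box can actually follow
  fixed <- (ub - lb) <= 1e-12
  free <- which(!fixed)
  emit_full <- function(free_rows) {
    out <- matrix(rep(v0_full, each = nrow(free_rows)), nrow = nrow(free_rows),
                  dimnames = list(NULL, rxn$id))
    out[, free] <- free_rows
    out
  }
  N <- if (length(free)) .null_space(S[, free, drop = FALSE]) else
    matrix(0, 0, 0)
  k <- ncol(N)
  if (k == 0) {
    samples <- matrix(rep(v0_full, each = n_samples), nrow = n_samples,
                      dimnames = list(NULL, rxn$id))
    return(.finish_sample_set(samples, mm, settings))
  }
  v0 <- v0_full[free]
  lb_all <- lb; ub_all <- ub
  lb <- lb[free]; ub <- ub[free]
  n <- length(free)
  warmup <- settings$warmup
  if (is.null(warmup)) warmup <- max(1000L, 10L * k)
  set.seed(settings$seed)
  # The chain lives in the k-dimensional null-space coordinates (alpha);
  # every position maps to v = v0 + N alpha, which satisfies S v = 0 exactly
  # up to one matrix product, so feasibility error cannot accumulate.
  alpha <- numeric(k)
  x <- v0
  center <- alpha
  n_seen <- 1
  buf_size <- 50L
  buffer <- matrix(0, buf_size, k)
  n_buf <- 1L
  samples <- matrix(NA_real_, n_samples, n)
  total_steps <- warmup + n_samples * settings$steps_per_point
  kept <- 0L
  eps_dir <- 1e-12
  for (step in seq_len(total_steps)) {
    if (step <= warmup || n_buf < 2L) {
      u <- stats::rnorm(k)
    } else {
      u <- buffer[sample.int(n_buf, 1L), ] - center
    }
    nu <- sqrt(sum(u * u))
    theta <- 0
    if (nu >= eps_dir) {
      u <- u / nu
      d <- as.numeric(N %*% u)   # unit vector (N orthonormal)
      pos <- d > eps_dir
      neg <- d < -eps_dir
      if (any(pos | neg)) {
        th_hi <- min((ub[pos] - x[pos]) / d[pos], (lb[neg] - x[neg]) / d[neg])
        th_lo <- max((lb[pos] - x[pos]) / d[pos], (ub[neg] - x[neg]) / d[neg])
        # a pinched segment (degenerate face) yields a zero-length move
        if (th_hi >= th_lo) theta <- stats::runif(1, th_lo, th_hi)
      }
    }
    alpha <- alpha + theta * u
    x <- v0 + as.numeric(N %*% alpha)
    n_seen <- n_seen + 1
    center <- center + (alpha - center) / n_seen
    slot <- if (n_buf < buf_size) n_buf + 1L else sample.int(buf_size, 1L)
    buffer[slot, ] <- alpha
    n_buf <- min(n_buf + 1L, buf_size)
    if (step > warmup && (step - warmup) %% settings$steps_per_point == 0L) {
      kept <- kept + 1L
      samples[kept, ] <- pmin(pmax(x, lb), ub)
      if (kept == n_samples) break
    }
  }
  if (kept < n_samples) samples <- samples[seq_len(kept), , drop = FALSE]
  .finish_sample_set(emit_full(samples), mm, settings)
}

.finish_sample_set <- function(samples, mm, settings) {
  tol <- settings$steady_state_tolerance
  resid <- max(abs(samples %*% t(as.matrix(mm$stoich))))
  lb <- mm$reactions$lb; ub <- mm$reactions$ub
  tv <- t(samples)  # reactions x samples: recycling compares against bounds
  ok_bounds <- all(tv >= lb - tol) && all(tv <= ub + tol)
  if (resid > tol || !ok_bounds) {
    stop("sampler produced infeasible rows (max |S v| = ", format(resid), ")")
  }
  structure(list(samples = samples,
                 reaction_ids = colnames(samples),
                 provenance = list(settings = settings, model = model_digest(mm))),
            class = "flux_sample_set")
}

#' @export
print.flux_sample_set <- function(x, ...) {
  cat("<flux_sample_set> ", nrow(x$samples), " samples x ",
      ncol(x$samples), " reactions (seed ",
      x$provenance$settings$seed, ")\n", sep = "")
  invisible(x)
}

#' Impose a basal growth constraint before sampling
#'
#' Sets the biomass lower bound to `fraction` times the model's FBA optimum,
#' excluding zero-growth states from the sampled polytope.
#'
#' @param model a `metabolic_model` or `community_model`.
#' @param biomass_id biomass reaction id; defaults to the model's first.
#' @param fraction basal fraction of the FBA optimum (default 0.1).
#' @return a modified copy, with the optimum recorded in the
#'   `"basal_provenance"` attribute.  When the FBA optimum is zero the model
#'   is returned unchanged with a warning.
#' @export
constrain_basal_growth <- function(model, biomass_id = NULL, fraction = 0.1) {
  mm <- as_metabolic_model(model)
  if (is.null(biomass_id)) biomass_id <- mm$biomass_ids[[1]]
  g <- solve_fba(mm, biomass_id)$objective_value
  if (g <= 0) {
    warning("FBA optimum is zero; basal bound left at zero")
  } else if (fraction > 0) {
    j <- match(biomass_id, mm$reactions$id)
    mm$reactions$lb[j] <- fraction * g
  }
  out <- if (inherits(model, "community_model")) { model$model <- mm; model } else mm
  attr(out, "basal_provenance") <- list(biomass_id = biomass_id,
                                        optimum = g, fraction = fraction)
  out
}

#' Convergence diagnostics for a flux sample set
#'
#' Split-half mean discrepancies and a lag-1 autocorrelation effective sample
#' size proxy per reaction.  Reactions whose split-half means differ by more
#' than `flag_multiple` times the split standard error are flagged.  The
#' diagnostic is advisory: short chains on high-dimensional polytopes are
#' expected to flag.
#'
#' @param sample_set a `flux_sample_set` with at least 10 samples.
#' @param flag_multiple multiple of the split standard error used to flag.
#' @return data.frame with columns `reaction`, `mean_first`, `mean_second`,
#'   `discrepancy`, `se`, `ess`, `flagged`.
#' @export
convergence_diagnostics <- function(sample_set, flag_multiple = 3) {
  X <- sample_set$samples
  n <- nrow(X)
  stopifnot(n >= 10)
  h <- n %/% 2
  first <- X[seq_len(h), , drop = FALSE]
  second <- X[(h + 1):n, , drop = FALSE]
  m1 <- colMeans(first); m2 <- colMeans(second)
  se <- sqrt(apply(first, 2, stats::var) / h + apply(second, 2, stats::var) / (n - h))
  disc <- abs(m1 - m2)
  ess <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j]
    if (stats::sd(v) < 1e-12) return(as.numeric(n))
    r1 <- stats::cor(v[-1], v[-n])
    max(1, n * (1 - abs(r1)) / (1 + abs(r1)))
  }, 0)
  flagged <- ifelse(se > 1e-12, disc > flag_multiple * se, disc > 1e-9)
  data.frame(reaction = colnames(X), mean_first = m1, mean_second = m2,
             discrepancy = disc, se = se, ess = ess, flagged = flagged,
             row.names = NULL, stringsAsFactors = FALSE)
}
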