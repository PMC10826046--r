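# Dense bounded-variable linear programming.
#
# A two-phase revised simplex over variables with individual (possibly
# infinite) bounds.  Equality rows are the native constraint form (the
# steady-state condition S v = 0); inequality rows are accepted and converted
# to equalities with slack variables.  Bland's rule is used throughout, which
# trades speed for a cycling-free guarantee -- the right trade at the model
# sizes this package works with (tens to a few hundred variables).

#' Solve a bounded linear program
#'
#' Maximizes (or minimizes) \code{obj \%*\% x} subject to
#' \code{A_eq x = b_eq}, \code{A_le x <= b_le} and \code{lb <= x <= ub}.
#' Bounds may be \code{-Inf}/\code{Inf}.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A_eq,b_eq equality constraint matrix and right-hand side
#'   (\code{A_eq} may be \code{NULL} for none).
#' @param A_le,b_le optional inequality (\code{<=}) constraints.
#' @param lb,ub variable bounds, recycled to length n.
#' @param maximize logical; maximize when \code{TRUE} (default).
#' @param tol numeric tolerance for pricing and feasibility decisions.
#' @return a list with elements \code{status} (one of \code{"optimal"},
#'   \code{"infeasible"}, \code{"unbounded"}), \code{x} (primal solution for
#'   the original n variables, or \code{NULL}) and \code{objective}.
#' @keywords internal
lp_solve <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lb = -Inf, ub = Inf, maximize = TRUE, tol = 1e-9) {
  n0 <- length(obj)
  lb <- rep_len(as.numeric(lb), n0)
  ub <- rep_len(as.numeric(ub), n0)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  A <- NULL
  b <- numeric(0)
  if (!is.null(A_eq)) {
    A_eq <- as.matrix(A_eq)
    A <- A_eq
    b <- as.numeric(b_eq)
  }
  n_slack <- 0L
  if (!is.null(A_le)) {
    A_le <- as.matrix(A_le)
    n_slack <- nrow(A_le)
    Sl <- diag(1, n_slack)
    top <- if (is.null(A)) NULL else cbind(A, matrix(0, nrow(A), n_slack))
    A <- rbind(top, cbind(A_le, Sl))
    b <- c(b, as.numeric(b_le))
    lb <- c(lb, rep(0, n_slack))
    ub <- c(ub, rep(Inf, n_slack))
  }
  if (is.null(A) || nrow(A) == 0L) {
    # pure box problem
    cc <- if (maximize) obj else -obj
    x <- ifelse(cc > 0, ub[seq_len(n0)], lb[seq_len(n0)])
    x[cc == 0] <- ifelse(is.finite(lb[seq_len(n0)][cc == 0]),
                         lb[seq_len(n0)][cc == 0],
                         pmin(ub[seq_len(n0)][cc == 0], 0))
    if (any(!is.finite(x) & cc != 0)) {
      return(list(status = "unbounded", x = NULL, objective = NA_real_))
    }
    return(list(status = "optimal", x = x, objective = sum(obj * x)))
  }
  cvec <- c(obj, rep(0, n_slack))
  if (!maximize) cvec <- -cvec
  res <- .simplex_bounded(cvec, A, b, lb, ub, tol)
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, objective = NA_real_))
  }
  x <- res$x[seq_len(n0)]
  list(status = "optimal", x = x, objective = sum(obj * x))
}

# Initial value for a nonbasic variable: the finite bound nearest zero, or 0
# for a free variable.
.nonbasic_start <- function(lb, ub) {
  x <- numeric(length(lb))
  at_l <- is.finite(lb)
  x[at_l] <- lb[at_l]
  only_u <- !at_l & is.finite(ub)
  x[only_u] <- ub[only_u]
  x
}

# Core bounded-variable simplex, maximization, equality rows only.
# Returns list(status, x).
.simplex_bounded <- function(cvec, A, b, lb, ub, tol) {
  m <- nrow(A)
  n <- ncol(A)
  x <- .nonbasic_start(lb, ub)
  r <- b - as.numeric(A %*% x)
  sg <- ifelse(r >= 0, 1, -1)
  # artificials: one per row, value |r_i|, bounds [0, Inf)
  Afull <- cbind(A, diag(sg, m))
  lbf <- c(lb, rep(0, m))
  ubf <- c(ub, rep(Inf, m))
  xf <- c(x, abs(r))
  basis <- n + seq_len(m)
  # status of nonbasic variables: "l", "u" or "f" (free, at 0)
  stat <- rep("b", n + m)
  stat[seq_len(n)] <- ifelse(is.finite(lb), "l", ifelse(is.finite(ub), "u", "f"))

  phase1 <- c(rep(0, n), rep(-1, m))
  out <- .simplex_iterate(phase1, Afull, lbf, ubf, xf, basis, stat, tol,
                          allow_unbounded = FALSE)
  if (out$status != "optimal") return(list(status = "infeasible", x = NULL))
  if (sum(out$x[n + seq_len(m)]) > sqrt(tol)) {
    return(list(status = "infeasible", x = NULL))
  }
  # pin artificials to zero (keeps redundant rows harmless) and run phase 2
  lbf[n + seq_len(m)] <- 0
  ubf[n + seq_len(m)] <- 0
  phase2 <- c(cvec, rep(0, m))
  out2 <- .simplex_iterate(phase2, Afull, lbf, ubf, out$x, out$basis, out$stat,
                           tol, allow_unbounded = TRUE)
  if (out2$status == "unbounded") return(list(status = "unbounded", x = NULL))
  list(status = "optimal", x = out2$x[seq_len(n)])
}

.simplex_iterate <- function(cvec, A, lb, ub, x, basis, stat, tol,
                             allow_unbounded, max_iter = 50000L) {
  m <- nrow(A)
  n <- ncol(A)
  rng_ok <- (ub - lb) > tol  # variable has room to move off its bound
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cvec[basis]), error = function(e) NULL)
    if (is.null(y)) stop("singular basis encountered in simplex", call. = FALSE)
    nonbasic <- which(stat != "b")
    d <- cvec[nonbasic] - as.numeric(t(y) %*% A[, nonbasic, drop = FALSE])
    st <- stat[nonbasic]
    up_ok <- (st == "l" | st == "f") & d > tol & rng_ok[nonbasic]
    dn_ok <- (st == "u" | st == "f") & d < -tol & rng_ok[nonbasic]
    elig <- which(up_ok | dn_ok)
    if (length(elig) == 0L) {
      return(list(status = "optimal", x = x, basis = basis, stat = stat))
    }
    j_rel <- elig[which.min(nonbasic[elig])]  # Bland: smallest variable index
    j <- nonbasic[j_rel]
    dirn <- if (up_ok[j_rel]) 1 else -1
    w <- solve(B, A[, j])           # basic response: xB <- xB - t*dirn*w
    # ratio test: entering moves by t >= 0 in direction dirn
    t_own <- if (dirn > 0) ub[j] - x[j] else x[j] - lb[j]
    lim <- rep(Inf, m)
    hit <- rep(NA_character_, m)
    for (i in seq_len(m)) {
      wi <- dirn * w[i]
      bi <- basis[i]
      if (wi > tol && is.finite(lb[bi])) {
        lim[i] <- (x[bi] - lb[bi]) / wi
        hit[i] <- "l"
      } else if (wi < -tol && is.finite(ub[bi])) {
        lim[i] <- (ub[bi] - x[bi]) / (-wi)
        hit[i] <- "u"
      }
    }
    t_star <- min(t_own, lim)
    if (!is.finite(t_star)) {
      if (allow_unbounded) return(list(status = "unbounded", x = NULL))
      stop("phase-1 subproblem unbounded; this should not happen", call. = FALSE)
    }
    t_star <- max(t_star, 0)
    if (t_own <= t_star + tol && t_own <= min(lim) + tol) {
      # bound flip: entering variable crosses to its opposite bound
      x[j] <- x[j] + dirn * t_own
      x[basis] <- x[basis] - t_own * dirn * w
      stat[j] <- if (dirn > 0) "u" else "l"
    } else {
      cand <- which(lim <= t_star + tol)
      leave <- cand[which.min(basis[cand])]  # Bland tie-break on leaving
      x[j] <- x[j] + dirn * t_star
      x[basis] <- x[basis] - t_star * dirn * w
      bi <- basis[leave]
      x[bi] <- if (hit[leave] == "l") lb[bi] else ub[bi]
      stat[bi] <- hit[leave]
      basis[leave] <- j
      stat[j] <- "b"
    }
  }
  stop("simplex iteration limit reached", call. = FALSE)
}
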