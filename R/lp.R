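# Dense bounded-variable two-phase primal simplex.
#
# Solves   max/min  obj' x   s.t.  A x = b,  lb <= x <= ub.
# Written for the small dense LPs arising from core metabolic networks
# (tens to a few hundred variables). Phase 1 uses one artificial variable
# per row, so rank-deficient constraint matrices (conserved moieties in
# stoichiometric matrices) are handled without preprocessing. Dantzig
# pricing with a permanent switch to Bland's rule after a stall guarantees
# termination under degeneracy.

.simplexSolve <- function(obj, A, b, lb, ub, maximize = TRUE,
                          tol = 1e-9, max_iter = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(lb > ub + tol)) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }
  cc <- if (maximize) as.numeric(obj) else -as.numeric(obj)

  # start nonbasic originals at a finite bound (free variables at 0)
  start_val <- ifelse(is.finite(lb), lb, ifelse(is.finite(ub), ub, 0))
  r0 <- b - as.vector(A %*% start_val)
  art_sign <- ifelse(r0 >= 0, 1, -1)

  Afull <- cbind(A, diag(art_sign, m))
  N <- n + m
  LB <- c(lb, rep(0, m))
  UB <- c(ub, rep(Inf, m))
  # stat: 0 basic, 1 at lower, 2 at upper, 3 free at 0
  stat <- integer(N)
  stat[seq_len(n)] <- ifelse(is.finite(lb), 1L, ifelse(is.finite(ub), 2L, 3L))
  basis <- n + seq_len(m)

  nbVal <- function(j, st) {
    ifelse(st[j] == 1L, LB[j], ifelse(st[j] == 2L, UB[j], 0))
  }

  runPhase <- function(cphase, eligible, basis, stat, iter_budget) {
    bland <- FALSE
    stall <- 0L
    last_obj <- -Inf
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > iter_budget) stop("simplex iteration limit reached", call. = FALSE)
      nonbasic <- which(stat != 0L)
      B <- Afull[, basis, drop = FALSE]
      xNv <- nbVal(nonbasic, stat)
      rhs <- b - as.vector(Afull[, nonbasic, drop = FALSE] %*% xNv)
      xB <- as.vector(solve(B, rhs))
      y <- as.vector(solve(t(B), cphase[basis]))
      cand <- nonbasic[eligible[nonbasic]]
      d <- cphase[cand] - as.vector(y %*% Afull[, cand, drop = FALSE])
      up <- (stat[cand] == 1L & d > tol) | (stat[cand] == 3L & d > tol)
      dn <- (stat[cand] == 2L & d < -tol) | (stat[cand] == 3L & d < -tol)
      ok <- up | dn
      if (!any(ok)) {
        objv <- sum(cphase[basis] * xB) + sum(cphase[nonbasic] * xNv)
        return(list(status = "optimal", basis = basis, stat = stat,
          xB = xB, objective = objv))
      }
      sel <- which(ok)
      t_idx <- if (bland) sel[which.min(cand[sel])] else sel[which.max(abs(d[sel]))]
      tj <- cand[t_idx]
      sigma <- if (up[t_idx]) 1 else -1
      w <- as.vector(solve(B, Afull[, tj]))

      # ratio test: entering moves by step >= 0 in direction sigma
      step_bb <- if (is.finite(LB[tj]) && is.finite(UB[tj])) UB[tj] - LB[tj] else Inf
      dec <- sigma * w        # basic i decreases by dec_i per unit step
      step <- step_bb; leave <- 0L; leave_to <- 0L
      for (i in seq_len(m)) {
        bi <- basis[i]
        if (dec[i] > tol) {
          lim <- if (is.finite(LB[bi])) (xB[i] - LB[bi]) / dec[i] else Inf
          if (lim < step - tol ||
              (lim < step + tol && (leave == 0L ||
                (bland && bi < basis[leave]) ||
                (!bland && abs(w[i]) > abs(w[leave]))))) {
            step <- max(lim, 0); leave <- i; leave_to <- 1L
          }
        } else if (dec[i] < -tol) {
          lim <- if (is.finite(UB[bi])) (UB[bi] - xB[i]) / (-dec[i]) else Inf
          if (lim < step - tol ||
              (lim < step + tol && (leave == 0L ||
                (bland && bi < basis[leave]) ||
                (!bland && abs(w[i]) > abs(w[leave]))))) {
            step <- max(lim, 0); leave <- i; leave_to <- 2L
          }
        }
      }
      if (!is.finite(step)) {
        return(list(status = "unbounded", basis = basis, stat = stat,
          xB = xB, objective = Inf))
      }
      objv <- sum(cphase[basis] * xB) + sum(cphase[nonbasic] * xNv)
      if (objv > last_obj + tol) { last_obj <- objv; stall <- 0L }
      else {
        stall <- stall + 1L
        if (stall > 200L) bland <- TRUE
      }
      if (leave == 0L) {
        # bound-to-bound flip of the entering variable
        stat[tj] <- if (stat[tj] == 1L) 2L else 1L
      } else {
        out <- basis[leave]
        stat[out] <- leave_to
        stat[tj] <- 0L
        basis[leave] <- tj
      }
    }
  }

  # phase 1: drive artificials to zero
  c1 <- c(rep(0, n), rep(-1, m))
  eligible1 <- rep(TRUE, N)
  p1 <- runPhase(c1, eligible1, basis, stat, max_iter)
  if (p1$status != "optimal" || p1$objective < -1e-7) {
    return(list(status = "infeasible", objective = NA_real_, x = NULL))
  }

  # phase 2: original objective, artificials pinned at zero
  UB[n + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  eligible2 <- c(rep(TRUE, n), rep(FALSE, m))
  p2 <- runPhase(c2, eligible2, p1$basis, p1$stat, max_iter)
  if (p2$status == "unbounded") {
    return(list(status = "unbounded", objective = if (maximize) Inf else -Inf, x = NULL))
  }

  x <- numeric(N)
  nb <- which(p2$stat != 0L)
  x[nb] <- nbVal(nb, p2$stat)
  x[p2$basis] <- p2$xB
  x <- x[seq_len(n)]
  # clip roundoff outside bounds
  x <- pmin(pmax(x, lb), ub)
  objv <- sum(as.numeric(obj) * x)
  list(status = "optimal", objective = objv, x = x)
}
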