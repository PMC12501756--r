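## Primal log-barrier interior-point method for the contribution program:
##   maximise r'n  s.t.  A n = b,  lb <= n <= ub,  n'Qn/2 <= qbar.
## Linear objective, convex quadratic constraint, box bounds, equality rows.
## Deterministic; used by solve_contributions().

## Newton minimisation of t*f0 + barrier subject to A x = b, from a strictly
## feasible x. f_grad_hess(x) must return list(val, grad, hess).
newton_eq <- function(x, A, f_grad_hess, tol = 1e-10, max_iter = 80) {
  n <- length(x)
  chol_jitter <- function(H) {
    jit <- 0
    for (k in 0:8) {
      ch <- tryCatch(chol(H + diag(jit, n)), error = function(e) NULL)
      if (!is.null(ch)) return(ch)
      jit <- max(jit * 100, 1e-12 * mean(diag(H)))
    }
    stop("barrier Hessian not positive definite")
  }
  for (it in seq_len(max_iter)) {
    f <- f_grad_hess(x)
    ## block elimination on the SPD barrier Hessian (KKT system with A dx = 0)
    ch <- chol_jitter(f$hess)
    Hig <- backsolve(ch, backsolve(ch, f$grad, transpose = TRUE))
    HiA <- backsolve(ch, backsolve(ch, t(A), transpose = TRUE))
    w <- solve(A %*% HiA, -A %*% Hig)
    dx <- as.numeric(-(Hig + HiA %*% w))
    lambda2 <- -sum(f$grad * dx)
    if (lambda2 / 2 < tol) return(x)
    ## backtracking line search keeping the barrier finite
    s <- 1; alpha <- 0.25; beta <- 0.5
    repeat {
      xn <- x + s * dx
      fn <- f_grad_hess(xn, value_only = TRUE)
      if (is.finite(fn) && fn <= f$val - alpha * s * lambda2) break
      s <- s * beta
      if (s < 1e-14) return(x)
    }
    x <- x + s * dx
  }
  x
}

## Barrier objective factory. obj_lin: minimise obj_lin'x; obj_quad: add
## 0.5 x'obj_quad x (phase 1 uses Q here). Inequalities: bounds and optional
## quadratic constraint x'Qx/2 + qlin'x <= qbar (the linear part arises from
## eliminated fixed variables).
barrier_fgh <- function(t, obj_lin, obj_quad, lb, ub, Q, qlin, qbar) {
  has_ub <- is.finite(ub)
  has_q <- is.finite(qbar) && !is.null(Q)
  function(x, value_only = FALSE) {
    dl <- x - lb
    du <- ub - x
    if (any(dl <= 0) || any(du[has_ub] <= 0)) {
      if (value_only) return(Inf)
      stop("infeasible point in barrier")
    }
    qx <- if (has_q) as.numeric(Q %*% x) + qlin else NULL
    slack <- if (has_q) qbar - sum(x * (qx + qlin)) / 2 else 1
    if (has_q && slack <= 0) {
      if (value_only) return(Inf)
      stop("infeasible point in barrier")
    }
    f0 <- sum(obj_lin * x) + if (!is.null(obj_quad)) sum(x * (obj_quad %*% x)) / 2 else 0
    val <- t * f0 - sum(log(dl)) - sum(log(du[has_ub])) - if (has_q) log(slack) else 0
    if (value_only) return(val)
    g0 <- obj_lin + if (!is.null(obj_quad)) as.numeric(obj_quad %*% x) else 0
    grad <- t * g0 + ifelse(has_ub, 1 / du, 0) - 1 / dl
    H <- diag(1 / dl^2 + ifelse(has_ub, 1 / du^2, 0), length(x))
    if (!is.null(obj_quad)) H <- H + t * obj_quad
    if (has_q) {
      grad <- grad + qx / slack
      H <- H + Q / slack + tcrossprod(qx) / slack^2
    }
    list(val = val, grad = grad, hess = H)
  }
}

## Central-path loop: returns x at duality gap (n_ineq / t) below gap_tol.
barrier_solve <- function(x0, A, obj_lin, obj_quad, lb, ub, Q = NULL,
                          qlin = 0, qbar = Inf,
                          gap_tol = 1e-10, mu = 20, t0 = 1) {
  n_ineq <- sum(is.finite(lb)) + sum(is.finite(ub)) + as.integer(is.finite(qbar))
  t <- t0
  x <- x0
  repeat {
    x <- newton_eq(x, A, barrier_fgh(t, obj_lin, obj_quad, lb, ub, Q, qlin, qbar))
    if (n_ineq / t < gap_tol) return(list(x = x, t = t))
    t <- t * mu
  }
}

## Strictly interior point satisfying A x = b (per-group sum rows) and
## lb < x < ub: x = lb + frac * (ub - lb) within each equality group.
interior_start <- function(groups, b, lb, ub) {
  x <- numeric(length(lb))
  ubf <- ifelse(is.finite(ub), ub, pmax(lb + 1, b[1] * 2 + 1))
  for (g in seq_along(groups)) {
    k <- groups[[g]]
    range_tot <- sum(ubf[k] - lb[k])
    need <- b[g] - sum(lb[k])
    if (need <= 0 || need >= range_tot) return(NULL)
    x[k] <- lb[k] + need * (ubf[k] - lb[k]) / range_tot
  }
  x
}
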