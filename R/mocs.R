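## Mendelian-sampling-based optimal contribution selection: the selection
## index, constraint calibration, the quadratically constrained contribution
## program, the VanRaden genomic relationship matrix, and mating allocation.

#' Usefulness-style selection index
#'
#' `I = b + 2 * x_p * sqrt(msv)`, combining a parent's breeding value with
#' its Mendelian standard deviation. `x_p` is the standard-normal truncation
#' point for a selected proportion `p` (the quantile with upper-tail mass
#' `p`), so `p = 0.5` gives `x_p = 0` and the index reduces to the breeding
#' value.
#'
#' @param b breeding value(s).
#' @param msv Mendelian sampling variance(s), `>= 0`.
#' @param p selected proportion in `(0, 1)`.
#' @return numeric index value(s).
#' @export
selection_index <- function(b, msv, p) {
  if (any(msv < 0)) stop("msv must be non-negative")
  if (p <= 0 || p >= 1) stop("selected proportion p must lie in (0, 1)")
  b + 2 * qnorm(p, lower.tail = FALSE) * sqrt(msv)
}

#' Calibrate the similarity constraint from a base population
#'
#' Scales a base-population similarity matrix (by its maximum element, its
#' maximum MSV, or not at all for an already standardised K) and returns the
#' requested percentile of the scaled off-diagonal similarity distribution as
#' the constraint level, to be reused unchanged in every later generation.
#'
#' @param S_base square similarity matrix of the base population.
#' @param percentile percentile in `(0, 100]` of the off-diagonal values.
#' @param scale_mode `"max"` (whole-matrix maximum, default), `"max_msv"`
#'   (maximum diagonal element) or `"none"`.
#' @param form how the percentile maps onto the bound for the quadratic form
#'   `n'Qn/2`. With contributions summing to one, `n'Qn` is the
#'   contribution-weighted average similarity of the selected group, so
#'   `"average"` (default) sets `qbar = quantile / 2`: the selected group's
#'   average similarity may not exceed the chosen base-population quantile.
#'   `"quantile"` uses the raw quantile as the bound on `n'Qn/2` itself
#'   (a factor-2 looser constraint).
#' @return list with `qbar` (the constraint), `scale`, `Q` (the scaled base
#'   matrix), `percentile`, `scale_mode` and `form`.
#' @export
calibrate_constraint <- function(S_base, percentile,
                                 scale_mode = c("max", "max_msv", "none"),
                                 form = c("average", "quantile")) {
  scale_mode <- match.arg(scale_mode)
  form <- match.arg(form)
  X <- unclass(S_base)
  if (nrow(X) < 2L) stop("base matrix must contain at least two entities")
  scale <- switch(scale_mode,
                  max = max(X), max_msv = max(diag(X)), none = 1)
  if (scale <= 0) stop("degenerate all-zero similarity matrix")
  Xs <- X / scale
  off <- Xs[lower.tri(Xs)]
  q <- as.numeric(quantile(off, percentile / 100, names = FALSE))
  qbar <- if (form == "average") q / 2 else q
  list(qbar = qbar, scale = scale, Q = Xs, percentile = percentile,
       scale_mode = scale_mode, form = form)
}

#' Contribution optimisation problem
#'
#' Bundles the ingredients of the contribution program: maximise the expected
#' genetic return `n'r` over contributions `n` subject to
#' `n'Qn/2 <= qbar`, the sex sums `n'v_f = 1/2`, `n'v_m = 1/2`, and bounds
#' `lb <= n <= ub`. `Q` may be a similarity matrix (S or K) or a genomic
#' relationship matrix.
#'
#' @param r selection criterion, one value per candidate (named).
#' @param Q symmetric constraint matrix, candidates x candidates.
#' @param qbar constraint level (may be `Inf` for an unconstrained program).
#' @param sex per-candidate sex, `"M"`/`"F"` (every candidate is one or the
#'   other).
#' @param lb,ub per-candidate bounds on contributions (recycled).
#' @param kind tag of the constraint matrix, `"S"`, `"K"` or `"GRM"`.
#' @return object of class `contribution_problem`.
#' @export
contribution_problem <- function(r, Q, qbar, sex, lb = 0, ub = Inf,
                                 kind = c("S", "K", "GRM")) {
  kind <- match.arg(kind)
  n <- length(r)
  Q <- unclass(Q)
  if (!is.matrix(Q) || any(dim(Q) != n)) stop("Q must be square, one row per candidate")
  if (max(abs(Q - t(Q))) > 1e-8 * max(1, max(abs(Q)))) stop("Q must be symmetric")
  sex <- as.character(sex)
  if (length(sex) != n || !all(sex %in% c("M", "F")))
    stop('every candidate needs a sex label "M" or "F"')
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  if (any(lb > ub)) stop("lb must not exceed ub")
  ids <- names(r)
  if (is.null(ids)) ids <- paste0("cand", seq_len(n))
  structure(list(r = setNames(as.numeric(r), ids), Q = Q, qbar = qbar,
                 sex = sex, lb = lb, ub = ub, kind = kind),
            class = "contribution_problem")
}

#' Solve the contribution program
#'
#' Deterministic primal interior-point (log-barrier Newton) solution of the
#' linear-objective, quadratically constrained program defined by
#' [contribution_problem()]. A non-PSD `Q` is repaired with [near_pd()] when
#' `repair = TRUE`, otherwise rejected. Feasibility is established by
#' minimising the quadratic form first; an infeasible constraint level is
#' reported as such, never silently relaxed. Optional iterative adaptation
#' enforces a minimum/maximum number of males with non-negligible
#' contribution: above the maximum, the upper bounds of the
#' lowest-contributing males are tightened to zero and the program re-solved;
#' below the minimum, the best excluded males (by criterion, ties by id)
#' receive a small floor contribution.
#'
#' @param problem a [contribution_problem()].
#' @param repair repair a non-PSD constraint matrix via [near_pd()].
#' @param min_males,max_males optional bounds on the number of males selected
#'   (contribution above `support_eps`).
#' @param floor_contribution floor used when topping up to `min_males`
#'   (required if `min_males` is set).
#' @param support_eps contribution threshold defining "selected".
#' @param max_adapt maximum number of adaptation re-solves.
#' @param gap_tol target duality gap of the interior-point method.
#' @return object of class `contribution_solution`: list with `n`
#'   (contributions), `objective`, `quad_value`, `status`
#'   (`"optimal"`/`"infeasible"`), `n_selected` (per sex), `binding`,
#'   `kkt_residual`, `qbar`.
#' @export
solve_contributions <- function(problem, repair = TRUE,
                                min_males = NULL, max_males = NULL,
                                floor_contribution = NULL,
                                support_eps = 1e-6, max_adapt = 50,
                                gap_tol = 1e-10) {
  stopifnot(inherits(problem, "contribution_problem"))
  ev_min <- min(eigen(problem$Q, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(1, max(abs(problem$Q)))) {
    if (!repair) stop("constraint matrix is not positive semidefinite; ",
                      "set repair = TRUE to apply near_pd()")
    problem$Q <- near_pd(problem$Q)
  }
  lb <- problem$lb; ub <- problem$ub
  sol <- solve_qcqp_core(problem$r, problem$Q, problem$qbar, problem$sex,
                         lb, ub, gap_tol)
  males <- which(problem$sex == "M")
  if (!is.null(max_males) || !is.null(min_males)) {
    if (!is.null(min_males) && is.null(floor_contribution))
      stop("min_males requires floor_contribution")
    for (it in seq_len(max_adapt)) {
      if (sol$status != "optimal") break
      sel <- males[sol$n[males] > support_eps]
      if (!is.null(max_males) && length(sel) > max_males) {
        keep <- sel[order(-sol$n[sel], names(sol$n)[sel])][seq_len(max_males)]
        drop <- setdiff(sel, keep)
        ub[drop] <- 0; lb[drop] <- 0
      } else if (!is.null(min_males) && length(sel) < min_males) {
        pool <- setdiff(males, sel)
        pool <- pool[lb[pool] < floor_contribution & ub[pool] >= floor_contribution]
        if (!length(pool)) break
        add <- pool[order(-problem$r[pool], names(sol$n)[pool])]
        add <- add[seq_len(min(length(add), min_males - length(sel)))]
        lb[add] <- floor_contribution
      } else break
      sol <- solve_qcqp_core(problem$r, problem$Q, problem$qbar, problem$sex,
                             lb, ub, gap_tol)
    }
  }
  sol
}

## Core QCQP solve with fixed-variable elimination. Returns the solution list.
solve_qcqp_core <- function(r, Q, qbar, sex, lb, ub, gap_tol = 1e-10) {
  n <- length(r)
  ids <- names(r)
  fixed <- (ub - lb) < 1e-12
  xf <- lb
  free <- which(!fixed)
  done <- function(nfull, status) {
    kkt <- attr(nfull, "kkt_residual")
    nfull <- as.numeric(nfull)
    quad <- as.numeric(nfull %*% Q %*% nfull) / 2
    structure(list(
      n = setNames(pmax(nfull, 0), ids),
      objective = sum(r * nfull), quad_value = quad, status = status,
      n_selected = c(F = sum(sex == "F" & nfull > 1e-6),
                     M = sum(sex == "M" & nfull > 1e-6)),
      binding = is.finite(qbar) && (qbar - quad) < 1e-6 * max(1, abs(qbar)),
      kkt_residual = kkt, qbar = qbar),
      class = "contribution_solution")
  }
  groups <- list(F = intersect(free, which(sex == "F")),
                 M = intersect(free, which(sex == "M")))
  b <- c(F = 0.5 - sum(xf[sex == "F" & fixed]),
         M = 0.5 - sum(xf[sex == "M" & fixed]))
  for (g in c("F", "M")) if (!length(groups[[g]]) && abs(b[g]) > 1e-10) {
    nf <- xf; return(done(nf, "infeasible"))
  }
  groups <- groups[lengths(groups) > 0]
  A <- do.call(rbind, lapply(groups, function(k) {
    row <- numeric(length(free)); row[match(k, free)] <- 1; row
  }))
  bg <- b[names(groups)]
  idx <- match(seq_len(n)[free], seq_len(n))
  Qxx <- Q[free, free, drop = FALSE]
  qlin <- if (any(fixed)) as.numeric(Q[free, fixed, drop = FALSE] %*% xf[fixed]) else numeric(length(free))
  q0 <- if (any(fixed)) as.numeric(xf[fixed] %*% Q[fixed, fixed, drop = FALSE] %*% xf[fixed]) / 2 else 0
  qbar_adj <- qbar - q0

  x0 <- interior_start(lapply(groups, function(k) match(k, free)), bg,
                       lb[free], ub[free])
  if (is.null(x0)) { nf <- xf; nf[free] <- NA; return(done(xf, "infeasible")) }
  qval <- function(x) as.numeric(x %*% Qxx %*% x) / 2 + sum(qlin * x)
  if (is.finite(qbar)) {
    if (qval(x0) >= qbar_adj * (1 - 1e-10)) {
      ph1 <- barrier_solve(x0, A, obj_lin = qlin, obj_quad = Qxx,
                           lb = lb[free], ub = ub[free], gap_tol = 1e-9)
      if (qval(ph1$x) >= qbar_adj - 1e-12) {
        nf <- xf; nf[free] <- ph1$x
        return(done(nf, "infeasible"))
      }
      x0 <- ph1$x
    }
    res <- barrier_solve(x0, A, obj_lin = -r[free], obj_quad = NULL,
                         lb = lb[free], ub = ub[free],
                         Q = Qxx, qlin = qlin, qbar = qbar_adj,
                         gap_tol = gap_tol)
  } else {
    res <- barrier_solve(x0, A, obj_lin = -r[free], obj_quad = NULL,
                         lb = lb[free], ub = ub[free], gap_tol = gap_tol)
  }
  ## rescale within each sex group so the sum constraints hold to float
  ## precision (removes the interior-point drift of order gap_tol)
  for (g in names(groups)) {
    k <- match(groups[[g]], free)
    s <- sum(res$x[k])
    if (s > 0) res$x[k] <- res$x[k] * (bg[g] / s)
  }
  nf <- xf; nf[free] <- res$x
  ## stationarity residual of the KKT conditions at the final central point
  x <- res$x; t <- res$t
  lam_lb <- 1 / (t * (x - lb[free]))
  lam_ub <- ifelse(is.finite(ub[free]), 1 / (t * (ub[free] - x)), 0)
  g <- -r[free] - lam_lb + lam_ub
  if (is.finite(qbar)) {
    slack <- qbar_adj - qval(x)
    g <- g + (as.numeric(Qxx %*% x) + qlin) / (t * slack)
  }
  nu <- tryCatch(qr.solve(t(A), -g), error = function(e) rep(0, nrow(A)))
  attr(nf, "kkt_residual") <- max(abs(g + as.numeric(t(A) %*% nu)))
  done(nf, "optimal")
}

#' @export
print.contribution_solution <- function(x, ...) {
  cat("contribution_solution:", x$status,
      "| objective", format(x$objective, digits = 6),
      "| n'Qn/2", format(x$quad_value, digits = 6),
      if (isTRUE(x$binding)) "(binding)" else "", "\n")
  cat("  selected:", x$n_selected["M"], "males,", x$n_selected["F"], "females\n")
  invisible(x)
}

#' Genomic relationship matrix (VanRaden Method 1)
#'
#' `G = Z Z' / (2 * sum_k p_k (1 - p_k))` with `Z` the column-centred
#' reference-allele dosages (`dosage - 2 p_k`) and `p_k` the sample allele
#' frequencies. Monomorphic markers contribute nothing; input with no
#' polymorphic marker is rejected.
#'
#' @param pg a [phased_genotypes()] object.
#' @return symmetric individuals x individuals matrix.
#' @export
vanraden_grm <- function(pg) {
  D <- pg$h1 + pg$h2
  p <- colMeans(D) / 2
  het <- p * (1 - p)
  if (all(het == 0)) stop("all markers are monomorphic; GRM undefined")
  Z <- sweep(D, 2, 2 * p)
  tcrossprod(Z) / (2 * sum(het))
}

## Largest-remainder rounding of non-negative targets to integers with a
## fixed total; deterministic tie-break by index.
largest_remainder <- function(x, total) {
  fl <- floor(x)
  rem <- as.integer(round(total - sum(fl)))
  if (rem > 0) {
    ord <- order(-(x - fl), seq_along(x))
    fl[ord[seq_len(rem)]] <- fl[ord[seq_len(rem)]] + 1
  }
  as.integer(fl)
}

#' Allocate matings from optimised contributions
#'
#' Converts male contributions into per-male mating counts by
#' largest-remainder rounding of `contribution / sum * n_females`, applies
#' the cap on females per male (excess redistributed to uncapped males),
#' checks the minimum number of distinct sires, and randomises the assignment
#' of males to females with an explicit seed. Each female receives exactly
#' one mating.
#'
#' @param contributions named non-negative contributions of the males.
#' @param females character vector of female ids (one mating each).
#' @param max_per_male cap on matings per male.
#' @param min_males minimum number of distinct sires required.
#' @param seed integer seed driving the shuffle.
#' @return data.frame with columns `sire`, `dam`, one row per mating.
#' @export
allocate_matings <- function(contributions, females, max_per_male = 50,
                             min_males = 5, seed = 1) {
  if (any(contributions < 0)) stop("contributions must be non-negative")
  Fn <- length(females)
  if (Fn > length(contributions[contributions > 0]) * max_per_male)
    stop("rule violated: max_per_male * positive males < number of females")
  target <- contributions / sum(contributions) * Fn
  counts <- largest_remainder(target, Fn)
  repeat {
    over <- counts > max_per_male
    if (!any(over)) break
    excess <- sum(counts[over] - max_per_male)
    counts[over] <- max_per_male
    open <- !over & counts < max_per_male
    if (!any(open)) stop("rule violated: max_per_male unsatisfiable")
    w <- contributions[open]
    if (sum(w) <= 0) w <- rep(1, sum(open))
    add <- largest_remainder(w / sum(w) * excess, excess)
    counts[open] <- counts[open] + add
  }
  if (sum(counts > 0) < min_males)
    stop("rule violated: fewer than min_males (", min_males, ") distinct sires")
  sires <- rep(names(contributions), counts)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  data.frame(sire = sample(sires), dam = females, stringsAsFactors = FALSE)
}
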