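test_that("selection index combines breeding value and Mendelian SD", {
  expect_equal(selection_index(3.2, 4, 0.5), 3.2)
  expect_equal(selection_index(0, 1, 0.01), 2 * qnorm(0.99), tolerance = 1e-9)
  expect_equal(selection_index(1.5, 0, 0.1), 1.5)
  expect_error(selection_index(0, -1, 0.1), "non-negative")
  expect_error(selection_index(0, 1, 1), "proportion")
})

test_that("constraint calibration scales and takes off-diagonal percentiles", {
  S <- build_S(table1$pg, table1$effects, table1$map)
  cal <- calibrate_constraint(S, 50, "max", form = "quantile")
  expect_equal(cal$scale, 0.3461, tolerance = 1e-12)
  expect_equal(cal$qbar, 0.2449 / 0.3461, tolerance = 1e-12)
  # a single off-diagonal value is every percentile
  expect_equal(calibrate_constraint(S, 100, "max", form = "quantile")$qbar,
               cal$qbar)
  expect_equal(calibrate_constraint(S, 0, "max", form = "quantile")$qbar,
               cal$qbar)
  # default form bounds the weighted average similarity: half the quantile
  expect_equal(calibrate_constraint(S, 50, "max")$qbar, cal$qbar / 2)
  expect_equal(calibrate_constraint(S, 30, "max_msv")$scale, 0.3461)
  expect_equal(calibrate_constraint(S, 30, "none")$scale, 1)
  X <- matrix(0, 3, 3)
  expect_error(calibrate_constraint(X, 50), "degenerate")
})

test_that("unconstrained optimisation piles mass on the best candidate per sex", {
  r <- c(m1 = 2, m2 = 1, m3 = 0.5, f1 = 1, f2 = 3)
  sex <- c("M", "M", "M", "F", "F")
  sol <- solve_contributions(contribution_problem(r, diag(5), Inf, sex))
  expect_equal(sol$status, "optimal")
  expect_equal(unname(sol$n[c("m1", "f2")]), c(0.5, 0.5), tolerance = 1e-6)
  expect_equal(sum(sol$n[sex == "M"]), 0.5, tolerance = 1e-8)
  expect_equal(sum(sol$n[sex == "F"]), 0.5, tolerance = 1e-8)
  # with upper bounds, the surplus flows to the next candidates
  sol2 <- solve_contributions(contribution_problem(r, diag(5), Inf, sex,
                                                   ub = 0.3))
  expect_equal(unname(sol2$n[c("m1", "m2", "m3")]), c(0.3, 0.2, 0),
               tolerance = 1e-6)
})

test_that("two identical males split their contribution symmetrically", {
  r <- c(a = 1, b = 1, f = 0)
  sol <- solve_contributions(contribution_problem(r, diag(3) * 0.1, Inf,
                                                  c("M", "M", "F")))
  expect_equal(unname(sol$n), c(0.25, 0.25, 0.5), tolerance = 1e-7)
})

test_that("solutions are feasible, KKT-consistent and match brute force", {
  set.seed(61)
  for (i in 1:5) {
    n_m <- 5; n <- 10
    r <- setNames(runif(n), paste0("c", 1:n))
    sex <- rep(c("M", "F"), each = n_m)
    Q <- crossprod(matrix(rnorm(n * n), n)) / n
    base <- solve_contributions(contribution_problem(r, Q, Inf, sex))
    qbar <- 0.6 * base$quad_value
    sol <- solve_contributions(contribution_problem(r, Q, qbar, sex))
    expect_equal(sol$status, "optimal")
    expect_lte(sol$quad_value, qbar + 1e-8)
    expect_gte(min(sol$n), -1e-12)
    expect_equal(sum(sol$n[sex == "M"]), 0.5, tolerance = 1e-8)
    expect_equal(sum(sol$n[sex == "F"]), 0.5, tolerance = 1e-8)
    gb <- grid_max(r, Q, qbar, n_m, step = 0.05)
    expect_gte(sol$objective, gb - 1e-3)
  }
})

test_that("the optimal objective is monotone in the constraint level", {
  set.seed(62)
  r <- setNames(runif(8), paste0("c", 1:8))
  sex <- rep(c("M", "F"), 4)
  Q <- crossprod(matrix(rnorm(64), 8)) / 8
  base <- solve_contributions(contribution_problem(r, Q, Inf, sex))
  grid <- seq(0.3, 1.5, by = 0.15) * base$quad_value
  objs <- vapply(grid, function(qb)
    solve_contributions(contribution_problem(r, Q, qb, sex))$objective,
    numeric(1))
  expect_true(all(diff(objs) >= -1e-6))
})

test_that("an unattainable constraint is reported infeasible, never relaxed", {
  r <- c(m = 1, f = 1)
  Q <- diag(2)
  sol <- solve_contributions(contribution_problem(r, Q, 1e-4, c("M", "F")))
  expect_equal(sol$status, "infeasible")
  # the only feasible point (0.5, 0.5) has n'Qn/2 = 0.25 > 1e-4
  expect_gt(sol$quad_value, 1e-4)
})

test_that("a non-PSD constraint matrix is repaired or rejected", {
  r <- c(m1 = 1, m2 = 0, f = 1)
  Q <- matrix(c(1, 2, 0, 2, 1, 0, 0, 0, 1), 3)
  pr <- contribution_problem(r, Q, 0.2, c("M", "M", "F"))
  expect_error(solve_contributions(pr, repair = FALSE), "positive semidefinite")
  sol <- solve_contributions(pr, repair = TRUE)
  expect_true(sol$status %in% c("optimal", "infeasible"))
})

test_that("tighter similarity constraints select more sires (tendency)", {
  set.seed(63)
  wins <- 0
  for (i in 1:20) {
    n_m <- 8
    r <- setNames(c(sort(runif(n_m), decreasing = TRUE), runif(4)),
                  paste0("c", 1:(n_m + 4)))
    sex <- rep(c("M", "F"), c(n_m, 4))
    B <- matrix(rnorm((n_m + 4) * 3), n_m + 4)
    Q <- tcrossprod(B) / 3 + diag(n_m + 4) * 0.1
    base <- solve_contributions(contribution_problem(r, Q, Inf, sex))
    loose <- solve_contributions(contribution_problem(r, Q, 0.9 * base$quad_value, sex))
    tight <- solve_contributions(contribution_problem(r, Q, 0.55 * base$quad_value, sex))
    if (tight$status == "optimal" && loose$status == "optimal" &&
        tight$n_selected["M"] >= loose$n_selected["M"]) wins <- wins + 1
  }
  expect_gte(wins, 14)
})

test_that("sire-count adaptation enforces the support bounds", {
  set.seed(64)
  n_m <- 10
  r <- setNames(c(runif(n_m), runif(4)), paste0("c", 1:(n_m + 4)))
  sex <- rep(c("M", "F"), c(n_m, 4))
  Q <- crossprod(matrix(rnorm((n_m + 4)^2), n_m + 4)) / (n_m + 4)
  base <- solve_contributions(contribution_problem(r, Q, Inf, sex))
  pr <- contribution_problem(r, Q, 0.5 * base$quad_value, sex)
  capped <- solve_contributions(pr, max_males = 3)
  if (capped$status == "optimal")
    expect_lte(sum(capped$n[sex == "M"] > 1e-6), 3)
  floored <- solve_contributions(pr, min_males = 6, floor_contribution = 0.01)
  if (floored$status == "optimal")
    expect_gte(sum(floored$n[sex == "M"] > 1e-6), 6)
})

test_that("VanRaden method 1 GRM follows its closed forms", {
  L <- 6
  mk <- paste0("m", 1:L)
  # all-heterozygous pair: p = 0.5 everywhere, Z = 0, G = 0
  h1 <- matrix(1L, 2, L, dimnames = list(c("a", "b"), mk))
  pg <- phased_genotypes(h1, 0L * h1)
  G <- vanraden_grm(pg)
  expect_equal(unname(G), matrix(0, 2, 2))
  # one hom-ref and one hom-alt individual: p = 0.5, Z = +-1, G = +-2
  pg2 <- phased_genotypes(rbind(a = rep(1L, L), b = rep(0L, L)),
                          rbind(a = rep(1L, L), b = rep(0L, L)))
  colnames(pg2$h1) <- colnames(pg2$h2) <- mk
  G2 <- vanraden_grm(pg2)
  expect_equal(unname(G2), matrix(c(2, -2, -2, 2), 2))
  # column centering
  set.seed(65)
  inst <- random_instance(L = 20, n_parents = 10)
  D <- inst$pg$h1 + inst$pg$h2
  Z <- sweep(D, 2, colMeans(D))
  expect_equal(unname(colMeans(Z)), rep(0, 20))
  mono <- phased_genotypes(matrix(1L, 2, 3), matrix(1L, 2, 3))
  expect_error(vanraden_grm(mono), "monomorphic")
})

test_that("mating allocation rounds, caps and randomises reproducibly", {
  females <- paste0("f", 1:250)
  eq <- allocate_matings(setNames(rep(0.1, 5), paste0("m", 1:5)), females,
                         seed = 3)
  expect_equal(unname(table(eq$sire)[paste0("m", 1:5)]), rep(50L, 5),
               ignore_attr = TRUE)
  expect_setequal(eq$dam, females)
  # cap redistribution: contributions (0.3, 0.1, 0.05, 0.03, 0.02) x 250
  contrib <- setNames(c(0.3, 0.1, 0.05, 0.03, 0.02), paste0("m", 1:5))
  al <- allocate_matings(contrib, females, max_per_male = 50, seed = 9)
  counts <- table(al$sire)[paste0("m", 1:5)]
  expect_equal(unname(counts), c(50, 50, 50, 50, 50), ignore_attr = TRUE)
  # determinism
  expect_identical(allocate_matings(contrib, females, seed = 11),
                   allocate_matings(contrib, females, seed = 11))
  expect_error(allocate_matings(setNames(c(1, 1), c("a", "b")), paste0("f", 1:10),
                                max_per_male = 50, min_males = 5, seed = 1),
               "min_males")
})
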