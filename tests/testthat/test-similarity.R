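Rl1 <- build_R_list(table1$map)
se1 <- signed_effects(table1$pg, table1$effects, "parent1")
se2 <- signed_effects(table1$pg, table1$effects, "parent2")

test_that("worked-example similarity equals the matched-gamete covariance", {
  expect_equal(pairwise_similarity(se1, se2, Rl1, table1$map), 0.2449,
               tolerance = 1e-12)
  # self-similarity equals the MSV
  expect_equal(pairwise_similarity(se1, se1, Rl1, table1$map), 0.3461,
               tolerance = 1e-12)
})

test_that("monozygotic twins have standardised similarity one", {
  pg <- phased_genotypes(table1$pg$h1[c(1, 1), ], table1$pg$h2[c(1, 1), ])
  S <- build_S(pg, table1$effects, table1$map)
  K <- standardize_similarity(S)
  expect_equal(K[1, 2], 1, tolerance = 1e-12)
  # ... even when one twin's haplotypes are swapped
  pg2 <- phased_genotypes(rbind(table1$pg$h1[1, ], table1$pg$h2[1, ]),
                          rbind(table1$pg$h2[1, ], table1$pg$h1[1, ]))
  K2 <- standardize_similarity(build_S(pg2, table1$effects, table1$map))
  expect_equal(K2[1, 2], 1, tolerance = 1e-12)
})

test_that("similarities are invariant under every per-chromosome haplotype flip", {
  set.seed(41)
  inst <- random_instance(L = 8, n_chrom = 2, n_parents = 2)
  Rl <- build_R_list(inst$map)
  ref <- NULL
  chroms <- unique(inst$map$chrom)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 2 * length(chroms)))
  for (r in seq_len(nrow(combos))) {
    pg <- inst$pg
    k <- 1
    for (p in c("p1", "p2")) for (cc in chroms) {
      if (combos[r, k]) pg <- flip_haplotypes(pg, p, inst$map, cc)
      k <- k + 1
    }
    a <- signed_effects(pg, inst$effects, "p1")
    b <- signed_effects(pg, inst$effects, "p2")
    val <- c(pairwise_similarity(a, b, Rl, inst$map),
             gamete_msv(a, Rl, inst$map), gamete_msv(b, Rl, inst$map),
             zygotic_similarity(a, b, b, a, Rl, inst$map))
    if (is.null(ref)) ref <- val else expect_equal(val, ref, tolerance = 1e-12)
  }
})

test_that("similarity matches the absolute oracle covariance", {
  set.seed(42)
  for (i in 1:40) {
    inst <- random_instance(L = sample(3:10, 1), n_chrom = 1, n_parents = 2)
    Rl <- build_R_list(inst$map)
    a <- signed_effects(inst$pg, inst$effects, "p1")
    b <- signed_effects(inst$pg, inst$effects, "p2")
    orc <- oracle_by_chrom(inst)
    expect_equal(pairwise_similarity(a, b, Rl, inst$map),
                 unname(orc$cov["p1", "p2"]), tolerance = 1e-10)
  }
})

test_that("Cauchy-Schwarz bounds the standardised similarity", {
  set.seed(43)
  for (i in 1:20) {
    inst <- random_instance(L = 12, n_chrom = 2, n_parents = 6)
    S <- build_S(inst$pg, inst$effects, inst$map)
    d <- diag(unclass(S))
    if (any(d <= 1e-12)) next
    K <- standardize_similarity(S)
    expect_equal(unname(diag(unclass(K))), rep(1, nrow(K)))
    off <- unclass(K)[upper.tri(K)]
    expect_true(all(off >= 0 & off <= 1 + 1e-12))
  }
})

test_that("Cholesky factor view reproduces the per-chromosome contribution", {
  set.seed(44)
  inst <- random_instance(L = 8, n_chrom = 1, n_parents = 2)
  R <- build_R(inst$map, unique(inst$map$chrom))
  L <- t(chol(R))
  a <- drop(signed_effects(inst$pg, inst$effects, "p1")$M)
  b <- drop(signed_effects(inst$pg, inst$effects, "p2")$M)
  expect_equal(sum((t(L) %*% a) * (t(L) %*% b)),
               drop(a %*% R %*% b), tolerance = 1e-12)
})

test_that("aggregate similarity reduces and scales as a bilinear form", {
  m <- unclass(table1$effects)
  eff2 <- marker_effects(rbind(m, 2 * m), markers = colnames(m))
  M1 <- signed_effects(table1$pg, eff2, "parent1")
  M2 <- signed_effects(table1$pg, eff2, "parent2")
  s1 <- pairwise_similarity(se1, se2, Rl1, table1$map)
  expect_equal(aggregate_similarity(M1, M2, Rl1, table1$map, c(1, 0)), s1,
               tolerance = 1e-12)
  # proportional trait rows m and 2m with a = (1, 1): factor (1 + 2)^2
  expect_equal(aggregate_similarity(M1, M2, Rl1, table1$map, c(1, 1)), 9 * s1,
               tolerance = 1e-12)
  expect_identical(aggregate_similarity(M1, M2, Rl1, table1$map, c(0, 0)), 0)
})

test_that("zygotic similarity decomposes into positional parent matches", {
  expect_equal(zygotic_similarity(se1, se2, se1, se2, Rl1, table1$map),
               0.5298, tolerance = 1e-12)
  hom <- phased_genotypes(matrix(1L, 2, 3, dimnames = list(c("u", "v"), paste0("m", 1:3))),
                          matrix(1L, 2, 3))
  su <- signed_effects(hom, table1$effects, "u")
  sv <- signed_effects(hom, table1$effects, "v")
  expect_identical(zygotic_similarity(se1, se2, su, sv, Rl1, table1$map), 0)
  set.seed(45)
  inst <- random_instance(L = 8, n_chrom = 2, n_parents = 4)
  Rl <- build_R_list(inst$map)
  ses <- lapply(individuals(inst$pg), function(p)
    signed_effects(inst$pg, inst$effects, p))
  expect_equal(zygotic_similarity(ses[[1]], ses[[2]], ses[[3]], ses[[4]], Rl, inst$map),
               pairwise_similarity(ses[[1]], ses[[3]], Rl, inst$map) +
                 pairwise_similarity(ses[[2]], ses[[4]], Rl, inst$map))
})

test_that("build_S assembles gametic and zygotic matrices consistently", {
  S <- build_S(table1$pg, table1$effects, table1$map)
  expect_equal(unclass(S),
               matrix(c(0.3461, 0.2449, 0.2449, 0.1837), 2,
                      dimnames = list(c("parent1", "parent2"),
                                      c("parent1", "parent2"))),
               tolerance = 1e-12, ignore_attr = TRUE)
  # permuting parents permutes S congruently
  pg_rev <- phased_genotypes(table1$pg$h1[2:1, ], table1$pg$h2[2:1, ])
  S_rev <- build_S(pg_rev, table1$effects, table1$map)
  expect_equal(unclass(S_rev), unclass(S)[2:1, 2:1], ignore_attr = TRUE)
  # one-parent population: 1x1 MSV
  pg1 <- phased_genotypes(table1$pg$h1[1, , drop = FALSE],
                          table1$pg$h2[1, , drop = FALSE])
  expect_equal(drop(unclass(build_S(pg1, table1$effects, table1$map))), 0.3461,
               tolerance = 1e-12, ignore_attr = TRUE)
  # zygotic diagonal equals the zygote MSV
  pairs <- cbind(c("parent1", "parent2"), c("parent2", "parent1"))
  Sz <- build_S(table1$pg, table1$effects, table1$map, mode = "zygotic",
                pairs = pairs)
  expect_equal(unname(diag(unclass(Sz))), rep(0.5298, 2), tolerance = 1e-12)
  expect_error(build_S(table1$pg, table1$effects, table1$map, mode = "zygotic"),
               "pairs")
})

test_that("standardisation rescales by Mendelian standard deviations", {
  S <- build_S(table1$pg, table1$effects, table1$map)
  K <- standardize_similarity(S)
  expect_equal(K[1, 2], 0.2449 / sqrt(0.3461 * 0.1837), tolerance = 1e-12)
  expect_equal(unname(diag(unclass(K))), c(1, 1))
  # zero-MSV entity: excluded with warning, or error on request
  X <- unclass(S)
  X[2, ] <- X[, 2] <- 0
  S0 <- structure(X, kind = "S", class = class(S))
  expect_warning(K0 <- standardize_similarity(S0), "parent2")
  expect_equal(dim(unclass(K0)), c(1L, 1L))
  expect_error(standardize_similarity(S0, exclude_zero = FALSE), "parent2")
})

test_that("near_pd clips eigenvalues and is idempotent on PSD input", {
  A <- matrix(c(1, 2, 2, 1), 2)
  B <- near_pd(A)
  expect_equal(B, matrix(1.5, 2, 2), tolerance = 1e-12)
  P <- crossprod(matrix(rnorm(16), 4))
  expect_equal(near_pd(P), P, tolerance = 1e-12)
  set.seed(46)
  for (i in 1:10) {
    X <- matrix(rnorm(400), 20); X <- (X + t(X)) / 2
    Y <- near_pd(X)
    ev <- eigen(Y, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-8 * max(ev))
    # Frobenius-nearest projection: cross-check against Matrix::nearPD
    ref <- as.matrix(Matrix::nearPD(X, eig.tol = 0, posd.tol = 0,
                                    conv.tol = 1e-12)$mat)
    expect_equal(Y, unname(ref), tolerance = 1e-5)
  }
  expect_error(near_pd(matrix(1:4, 2)), "symmetric")
})

test_that("shared heterozygosity diagnostics match their definitions", {
  expect_identical(shared_heterozygosity(table1$pg, "parent1", "parent2"), 3L)
  expect_equal(weighted_shared_effects(table1$pg, "parent1", "parent2",
                                       table1$effects),
               1 + 0.04 + 0.0004, tolerance = 1e-12)
  hom <- phased_genotypes(rbind(a = c(1L, 1L, 1L), b = c(0L, 0L, 0L)),
                          rbind(a = c(1L, 1L, 1L), b = c(0L, 0L, 0L)))
  colnames(hom$h1) <- colnames(hom$h2) <- paste0("m", 1:3)
  expect_identical(shared_heterozygosity(hom, "a", "b"), 0L)
  # unlinked identical-phase case: similarity = weighted shared effects / 4
  set.seed(47)
  L <- 8
  h1 <- matrix(1L, 2, L, dimnames = list(c("x", "y"), paste0("m", 1:L)))
  h2 <- matrix(rbinom(2 * L, 1, 0.4), 2, L)
  pg <- phased_genotypes(h1, h2)
  far <- genetic_map(rep("1", L), paste0("m", 1:L),
                     pos_morgan = seq(0, by = 60, length.out = L))
  eff <- marker_effects(rnorm(L), markers = paste0("m", 1:L))
  Rl <- build_R_list(far)
  a <- signed_effects(pg, eff, "x"); b <- signed_effects(pg, eff, "y")
  expect_equal(pairwise_similarity(a, b, Rl, far),
               weighted_shared_effects(pg, "x", "y", eff) / 4, tolerance = 1e-9)
})
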