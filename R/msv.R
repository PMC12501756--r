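## Mendelian sampling variances and covariance matrices for gametes and
## zygotes: single-trait, multi-trait and aggregate-genotype, all as quadratic
## or bilinear forms of signed effect vectors with the shared per-chromosome
## within-family LD matrices.

## Per-chromosome product A_c = M_ic R_c M_jc' (traits x traits), returned as
## a list over chromosomes. The workhorse for every MSV and similarity.
chrom_products <- function(Mi, Mj, R_list, cidx) {
  lapply(names(cidx), function(cc) {
    k <- cidx[[cc]]
    (Mi[, k, drop = FALSE] %*% R_list[[cc]]) %*% t(Mj[, k, drop = FALSE])
  })
}

se_matrix <- function(x) if (inherits(x, "signed_effects")) x$M else x

## Collapse a traits x markers signed matrix to the aggregate-genotype row
## vector w' = a'M (1 x markers).
aggregate_row <- function(M, a) {
  if (length(a) != nrow(M)) stop("index weights must have one entry per trait")
  matrix(as.numeric(a) %*% M, nrow = 1)
}

#' Gamete Mendelian sampling variance (single trait)
#'
#' The MSV of breeding values of gametes produced by a parent, as the
#' quadratic form `sum_c m_ic' R_c m_ic` of the parent's signed effect vector
#' with the per-chromosome within-family LD matrices. Always non-negative and
#' invariant to a global sign flip of the signed effects (haplotype order).
#'
#' @param m_i a [signed_effects()] object (or traits x markers matrix).
#' @param R_list per-chromosome R matrices from [build_R_list()].
#' @param map the [genetic_map()] the R matrices were built from.
#' @param trait trait row to use (index or name), default first.
#' @return non-negative scalar MSV in squared trait units.
#' @export
gamete_msv <- function(m_i, R_list, map, trait = 1L) {
  M <- se_matrix(m_i)[trait, , drop = FALSE]
  if (ncol(M) != nrow(map)) stop("signed effects and map have mismatched marker counts")
  sum(unlist(chrom_products(M, M, R_list, chrom_index(map))))
}

## Reference path (kept unexported as a validation oracle): the parent-specific
## covariance matrix R_i carries the linkage-phase signs, rho_kl^(i) =
## delta_ik * delta_il * exp(-2 d_kl)/4, with rows/columns of homozygous
## markers zeroed; the MSV is then m' R_i m with the unsigned population
## effects. Algebraically identical to gamete_msv.
build_R_bonk <- function(pg, map, parent, chrom) {
  R <- build_R(map, chrom)
  k <- map$chrom == as.character(chrom)
  delta <- (pg$h1[parent, ] - pg$h2[parent, ])[k]
  R * outer(delta, delta)
}

bonk_msv <- function(pg, effects, map, parent, trait = 1L) {
  check_aligned(pg, effects = effects, map = map)
  m <- unclass(effects)[trait, ]
  sum(vapply(unique(map$chrom), function(cc) {
    k <- map$chrom == cc
    mc <- m[k]
    as.numeric(mc %*% build_R_bonk(pg, map, parent, cc) %*% mc)
  }, numeric(1)))
}

#' Multi-trait Mendelian covariance matrix of gametes
#'
#' `V_i = sum_c M_ic R_c M_ic'`: diagonal entries are the per-trait gamete
#' MSVs, off-diagonals the Mendelian sampling covariances between traits.
#' Tiny negative eigenvalues from floating point are not altered in the
#' stored matrix; use [near_pd()] before factorising if needed.
#'
#' @inheritParams gamete_msv
#' @param M_i a [signed_effects()] object (all trait rows used).
#' @return symmetric traits x traits matrix of class `mendelian_covariance`
#'   with attributes `role = "gamete"` and `owner`.
#' @export
multitrait_V <- function(M_i, R_list, map) {
  M <- se_matrix(M_i)
  if (ncol(M) != nrow(map)) stop("signed effects and map have mismatched marker counts")
  V <- Reduce(`+`, chrom_products(M, M, R_list, chrom_index(map)))
  V <- (V + t(V)) / 2
  structure(V, role = "gamete",
            owner = if (inherits(M_i, "signed_effects")) M_i$parent else NA_character_,
            class = c("mendelian_covariance", "matrix", "array"))
}

#' Aggregate-genotype Mendelian sampling variance
#'
#' `a' V a` for a Mendelian covariance matrix `V` and index weights `a`.
#'
#' @param V traits x traits Mendelian covariance matrix.
#' @param a numeric index weights, one per trait.
#' @return non-negative scalar.
#' @export
aggregate_msv <- function(V, a) {
  if (length(a) != nrow(V)) stop("index weights must have one entry per trait")
  as.numeric(a %*% unclass(V) %*% a)
}

#' Zygote Mendelian sampling quantities
#'
#' The MSV of zygote breeding values from a mating is the sum of the two
#' parental gamete quantities: `var(b_ij) = m_i' R m_i + m_j' R m_j`
#' (single trait), `V_ij = sum_c M_ic R_c M_ic' + M_jc R_c M_jc'`
#' (multi-trait), and `a' V_ij a` (aggregate genotype).
#'
#' @inheritParams gamete_msv
#' @param m_i,m_j,M_i,M_j [signed_effects()] of the two parents.
#' @param V_ij zygote Mendelian covariance matrix from [zygote_V()].
#' @param a index weights.
#' @return scalar MSV, or traits x traits `mendelian_covariance` with
#'   `role = "zygote"`.
#' @export
zygote_msv <- function(m_i, m_j, R_list, map, trait = 1L) {
  gamete_msv(m_i, R_list, map, trait) + gamete_msv(m_j, R_list, map, trait)
}

#' @rdname zygote_msv
#' @export
zygote_V <- function(M_i, M_j, R_list, map) {
  V <- unclass(multitrait_V(M_i, R_list, map)) + unclass(multitrait_V(M_j, R_list, map))
  own <- paste(if (inherits(M_i, "signed_effects")) M_i$parent else "i",
               if (inherits(M_j, "signed_effects")) M_j$parent else "j", sep = "x")
  structure(V, role = "zygote", owner = own,
            class = c("mendelian_covariance", "matrix", "array"))
}

#' @rdname zygote_msv
#' @export
zygote_aggregate <- function(V_ij, a) aggregate_msv(V_ij, a)

#' MSVs for a whole population
#'
#' Convenience wrapper computing the gamete MSV (one trait or the aggregate
#' genotype) for every individual, sharing one set of R matrices.
#'
#' @inheritParams signed_effects
#' @param map a [genetic_map()] aligned with `pg`.
#' @param trait trait row, or `"aggregate"` to use the stored index weights.
#' @param R_list optional precomputed [build_R_list()] result.
#' @return named numeric vector of MSVs.
#' @export
population_msv <- function(pg, effects, map, trait = 1L, R_list = NULL) {
  check_aligned(pg, effects = effects, map = map)
  if (is.null(R_list)) R_list <- build_R_list(map)
  P <- signed_matrix(pg, effects, trait)
  cidx <- chrom_index(map)
  out <- numeric(nrow(P))
  for (cc in names(cidx)) {
    k <- cidx[[cc]]
    Pc <- P[, k, drop = FALSE]
    out <- out + rowSums((Pc %*% R_list[[cc]]) * Pc)
  }
  setNames(out, rownames(P))
}

## Stack the signed effect vectors of all individuals for one trait (or the
## aggregate genotype) into an individuals x markers matrix.
signed_matrix <- function(pg, effects, trait = 1L) {
  E <- unclass(effects)
  m <- if (identical(trait, "aggregate")) {
    a <- index_weights(effects)
    if (is.null(a)) stop("effects carry no index weights; cannot aggregate")
    as.numeric(a %*% E)
  } else E[trait, ]
  delta <- pg$h1 - pg$h2
  sweep(delta, 2, m, "*")
}
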