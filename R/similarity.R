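## Pairwise haplotype similarity between parents (gametic) and between parent
## pairs (zygotic), assembly into the similarity matrix S, standardisation
## into K, nearest-PSD repair, and the heterozygosity diagnostics.

#' Pairwise haplotype similarity of two parents
#'
#' The bilinear form of the two parents' signed effect vectors with the
#' within-family LD matrix, summed over chromosomes with the absolute value
#' taken per chromosome: `s_ij = sum_c | m_ic' R_c m_jc |`. The per-chromosome
#' absolute value makes the measure invariant to each parent's arbitrary
#' haplotype order. A parent's similarity to itself equals its gamete MSV.
#'
#' @inheritParams gamete_msv
#' @param m_i,m_j [signed_effects()] of the two parents.
#' @return non-negative scalar similarity (squared trait units).
#' @export
pairwise_similarity <- function(m_i, m_j, R_list, map, trait = 1L) {
  Mi <- se_matrix(m_i)[trait, , drop = FALSE]
  Mj <- se_matrix(m_j)[trait, , drop = FALSE]
  if (ncol(Mi) != nrow(map)) stop("signed effects and map have mismatched marker counts")
  sum(abs(unlist(chrom_products(Mi, Mj, R_list, chrom_index(map)))))
}

#' Aggregate-genotype similarity of two parents
#'
#' Same bilinear construction on the index-collapsed signed vectors
#' `w_i' = a' M_i`: `s_ij = sum_c | a' M_ic R_c M_jc' a |`, absolute value per
#' chromosome as in the single-trait case.
#'
#' @inheritParams pairwise_similarity
#' @param M_i,M_j [signed_effects()] of the two parents (all trait rows).
#' @param a numeric index weights, one per trait.
#' @export
aggregate_similarity <- function(M_i, M_j, R_list, map, a) {
  wi <- aggregate_row(se_matrix(M_i), a)
  wj <- aggregate_row(se_matrix(M_j), a)
  sum(abs(unlist(chrom_products(wi, wj, R_list, chrom_index(map)))))
}

#' Zygotic similarity between two parent pairs
#'
#' Similarity between the zygotes of pair (i, j) and pair (u, v), matching
#' parents positionally (sire with sire, dam with dam):
#' `s_ij,uv = sum_c (|m_ic' R_c m_uc| + |m_jc' R_c m_vc|)`, with the absolute
#' value applied per parental term per chromosome. The similarity of a pair
#' with itself equals the zygote MSV.
#'
#' @inheritParams pairwise_similarity
#' @param m_u,m_v [signed_effects()] of the second pair.
#' @param a optional index weights for the aggregate genotype; when supplied
#'   all trait rows are used.
#' @export
zygotic_similarity <- function(m_i, m_j, m_u, m_v, R_list, map, trait = 1L, a = NULL) {
  if (is.null(a)) {
    pairwise_similarity(m_i, m_u, R_list, map, trait) +
      pairwise_similarity(m_j, m_v, R_list, map, trait)
  } else {
    aggregate_similarity(m_i, m_u, R_list, map, a) +
      aggregate_similarity(m_j, m_v, R_list, map, a)
  }
}

#' Assemble a similarity matrix S
#'
#' Builds the trait-specific (or aggregate-genotype) similarity matrix over a
#' set of parents (`mode = "gametic"`: MSVs on the diagonal, pairwise
#' similarities off it) or over ordered parent pairs (`mode = "zygotic"`:
#' zygote MSVs on the diagonal). Deterministic given its inputs.
#'
#' @inheritParams population_msv
#' @param mode `"gametic"` or `"zygotic"`.
#' @param trait trait row, or `"aggregate"` for the index-weighted genotype.
#' @param pairs for zygotic mode, a two-column matrix or data.frame of
#'   (sire, dam) ids; entities are the pairs in row order.
#' @return object of class `similarity_matrix`: square matrix with entity ids
#'   as dimnames and attributes `kind = "S"`, `mode`, `trait`.
#' @export
build_S <- function(pg, effects, map, mode = c("gametic", "zygotic"),
                    trait = 1L, pairs = NULL, R_list = NULL) {
  mode <- match.arg(mode)
  check_aligned(pg, effects = effects, map = map)
  if (nrow(pg$h1) < 1L) stop("empty population")
  if (is.null(R_list)) R_list <- build_R_list(map)
  P <- signed_matrix(pg, effects, trait)
  cidx <- chrom_index(map)
  n <- nrow(P)
  G <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
  for (cc in names(cidx)) {
    k <- cidx[[cc]]
    Pc <- P[, k, drop = FALSE]
    G <- G + abs((Pc %*% R_list[[cc]]) %*% t(Pc))
  }
  G <- (G + t(G)) / 2
  if (mode == "gametic") {
    S <- G
  } else {
    if (is.null(pairs)) stop("zygotic mode requires a (sire, dam) pairs table")
    pairs <- as.matrix(pairs)
    if (ncol(pairs) != 2L) stop("pairs must have two columns (sire, dam)")
    sire <- as.character(pairs[, 1]); dam <- as.character(pairs[, 2])
    S <- G[sire, sire, drop = FALSE] + G[dam, dam, drop = FALSE]
    ids <- paste(sire, dam, sep = "x")
    dimnames(S) <- list(ids, ids)
  }
  structure(S, kind = "S", mode = mode,
            trait = if (identical(trait, "aggregate")) "aggregate"
            else rownames(unclass(effects))[trait],
            class = c("similarity_matrix", "matrix", "array"))
}

#' Standardise a similarity matrix
#'
#' `K = D^-1 S D^-1` with `D` the diagonal matrix of Mendelian standard
#' deviations (`D_ii = sqrt(S_ii)`), so `k_ij = s_ij / sqrt(s_ii s_jj)`.
#' K has unit diagonal and, by the per-chromosome Cauchy-Schwarz inequality,
#' off-diagonals in `[0, 1]`. Entities with MSV below `eps` carry no
#' Mendelian sampling information and are excluded with a warning (or raise
#' an error when `exclude_zero = FALSE`).
#'
#' @param S a similarity matrix from [build_S()] (kind `"S"`).
#' @param eps diagonal threshold below which an entity is degenerate.
#' @param exclude_zero drop degenerate entities (default) instead of erroring.
#' @return `similarity_matrix` of kind `"K"`.
#' @export
standardize_similarity <- function(S, eps = 1e-12, exclude_zero = TRUE) {
  d <- diag(unclass(S))
  bad <- d <= eps
  if (any(bad)) {
    if (!exclude_zero)
      stop("zero-MSV entities: ", paste(rownames(S)[bad], collapse = ", "))
    warning("excluding ", sum(bad), " zero-MSV entit",
            if (sum(bad) == 1) "y" else "ies", " from K: ",
            paste(rownames(S)[bad], collapse = ", "), call. = FALSE)
    S <- S[!bad, !bad, drop = FALSE]
    d <- d[!bad]
  }
  K <- unclass(S) / sqrt(outer(d, d))
  diag(K) <- 1
  structure(K, kind = "K", mode = attr(S, "mode"), trait = attr(S, "trait"),
            class = c("similarity_matrix", "matrix", "array"))
}

#' Nearest positive semidefinite matrix
#'
#' Projects a symmetric matrix onto the cone of positive semidefinite
#' matrices in the Frobenius norm by clipping negative eigenvalues at zero
#' (for an unconstrained projection the alternating-projections scheme
#' converges in this single step). Already-PSD input is returned unchanged up
#' to symmetrisation.
#'
#' @param x symmetric numeric matrix.
#' @param tol relative symmetry tolerance for the input check.
#' @return symmetric PSD matrix with the attributes of `x` preserved.
#' @export
near_pd <- function(x, tol = 1e-8) {
  X <- unclass(x)
  if (!is.matrix(X) || nrow(X) != ncol(X)) stop("input must be a square matrix")
  if (max(abs(X - t(X))) > tol * max(1, max(abs(X))))
    stop("input must be symmetric")
  X <- (X + t(X)) / 2
  e <- eigen(X, symmetric = TRUE)
  if (all(e$values >= 0)) return(x)
  Y <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  Y <- (Y + t(Y)) / 2
  attributes(Y) <- attributes(x)
  Y
}

#' Common-heterozygosity diagnostics
#'
#' `shared_heterozygosity` counts the markers at which both parents are
#' heterozygous; `weighted_shared_effects` sums the squared marker effects
#' over those markers. In the unlinked, identical-phase case
#' `weighted_shared_effects / 4` equals the pairwise similarity.
#'
#' @inheritParams signed_effects
#' @param i,j individual ids.
#' @param trait trait row for the effect weighting.
#' @return integer count, or numeric sum of squared effects.
#' @export
shared_heterozygosity <- function(pg, i, j) {
  delta <- phase_indicator(pg)
  sum(delta[i, ] != 0L & delta[j, ] != 0L)
}

#' @rdname shared_heterozygosity
#' @export
weighted_shared_effects <- function(pg, i, j, effects, trait = 1L) {
  check_aligned(pg, effects = effects)
  delta <- phase_indicator(pg)
  shared <- delta[i, ] != 0L & delta[j, ] != 0L
  sum(unclass(effects)[trait, shared]^2)
}
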