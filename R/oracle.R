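## Exhaustive enumeration of single-chromosome segregation patterns: gamete
## probabilities, transmitted breeding values and exact moments. Ground truth
## for the matrix expressions on small instances; exact or refuses.

MAX_ORACLE_LOCI <- 20L

## Accept parents as a phased_genotypes object (single chromosome) or a list
## of list(h1 =, h2 =) 0/1 vectors; returns list of 2 x L matrices.
as_haplo_list <- function(parents) {
  if (inherits(parents, "phased_genotypes")) {
    lapply(individuals(parents), function(id)
      rbind(parents$h1[id, ], parents$h2[id, ]))
  } else {
    lapply(parents, function(p) rbind(p$h1, p$h2))
  }
}

#' Enumerate segregation patterns of a single chromosome
#'
#' Lists all `2^L` gamete segregation patterns (sequences of parental
#' haplotype origins, `A` = first haplotype, `B` = second), their
#' probabilities `0.5 * prod(theta or 1 - theta)` over adjacent intervals,
#' and the breeding value each pattern transmits from each parent,
#' `0.5 * sum_k (+-m_k)` with the sign set by the transmitted allele.
#' Probabilities are accumulated in log space. Refuses more than 20 loci.
#'
#' @param theta recombination fractions between adjacent markers (length L-1).
#' @param parents a single-chromosome [phased_genotypes()] object, or a list
#'   of `list(h1 =, h2 =)` 0/1 allele vectors (1 = reference).
#' @param m numeric vector of additive marker effects (length L).
#' @return data.frame with columns `pattern`, `prob` and one `bv_<parent>`
#'   column per parent; `2^L` rows summing to probability 1.
#' @export
enumerate_patterns <- function(theta, parents, m) {
  haps <- as_haplo_list(parents)
  L <- length(m)
  if (L > MAX_ORACLE_LOCI)
    stop("refusing exhaustive enumeration beyond ", MAX_ORACLE_LOCI, " loci")
  if (length(theta) != L - 1L) stop("theta must have length L - 1")
  if (any(theta < 0) || any(theta >= 0.5)) stop("theta must lie in [0, 0.5)")
  if (any(vapply(haps, ncol, 1L) != L)) stop("parent haplotypes must have L loci")
  nm <- if (inherits(parents, "phased_genotypes")) individuals(parents)
        else if (!is.null(names(parents))) names(parents)
        else paste0("p", seq_along(haps))

  W <- 2L^L
  ## source[w, k] = 0 if pattern w transmits from haplotype A at locus k
  src <- matrix(0L, W, L)
  for (k in seq_len(L)) src[, k] <- bitwAnd(seq_len(W) - 1L, bitwShiftL(1L, k - 1L)) > 0L
  patt <- apply(src, 1, function(s) paste(c("A", "B")[s + 1L], collapse = "-"))

  logp <- rep(log(0.5), W)
  for (k in seq_len(L - 1L)) {
    sw <- src[, k] != src[, k + 1L]
    logp <- logp + ifelse(sw, log(theta[k]), log1p(-theta[k]))
  }
  prob <- exp(logp)

  out <- data.frame(pattern = patt, prob = prob, stringsAsFactors = FALSE)
  for (i in seq_along(haps)) {
    h <- haps[[i]]
    ## transmitted allele: h[1, k] if source A else h[2, k]; ref -> +m/2
    allele <- ifelse(src == 1L, rep(h[2, ], each = W), rep(h[1, ], each = W))
    out[[paste0("bv_", nm[i])]] <- as.numeric((2 * allele - 1) %*% m) / 2
  }
  out
}

#' Exact moments of the segregation-pattern distribution
#'
#' Means (always 0 by the A/B-swap symmetry), variances (the gamete MSVs) and
#' the covariance matrix of breeding values of matched-pattern gametes
#' between parents, all computed exactly from the enumeration.
#'
#' @param patterns output of [enumerate_patterns()].
#' @return list with `mean`, `var` (per parent) and `cov` (parents x parents
#'   matrix of matched-gamete covariances).
#' @export
oracle_moments <- function(patterns) {
  bcols <- grep("^bv_", names(patterns), value = TRUE)
  B <- as.matrix(patterns[bcols])
  p <- patterns$prob
  mu <- as.numeric(p %*% B)
  ctr <- sweep(B, 2, mu)
  cv <- t(ctr) %*% (ctr * p)
  nm <- sub("^bv_", "", bcols)
  dimnames(cv) <- list(nm, nm)
  list(mean = setNames(mu, nm), var = setNames(diag(cv), nm), cov = cv)
}

#' Zygote moments by exhaustive enumeration
#'
#' For a mating (i, j), enumerates all independent combinations of the two
#' parents' segregation patterns to give the exact zygote MSV, and for two
#' matings (i, j) vs (u, v) the pair-pair similarity
#' `|Cov(b_i, b_u)| + |Cov(b_j, b_v)|` from the matched-pattern distribution.
#'
#' @param patterns output of [enumerate_patterns()] covering all parents named.
#' @param pair_1 character vector `c(sire, dam)` of the first mating.
#' @param pair_2 optional second mating; when omitted the similarity reported
#'   is of `pair_1` with itself (its zygote MSV).
#' @return list with `zygote_msv` (of `pair_1`) and `similarity` (between the
#'   two matings).
#' @export
oracle_zygote <- function(patterns, pair_1, pair_2 = pair_1) {
  p <- patterns$prob
  if (length(p)^2 > 2^20) stop("combined enumeration exceeds 2^20 patterns")
  b <- function(id) patterns[[paste0("bv_", id)]]
  bi <- b(pair_1[1]); bj <- b(pair_1[2])
  ## independent draws (w1, w2): var over the product distribution
  Z <- outer(bi, bj, "+")
  P <- outer(p, p)
  mu <- sum(P * Z)
  zmsv <- sum(P * (Z - mu)^2)
  cv <- function(x, y) sum(p * x * y) - sum(p * x) * sum(p * y)
  sim <- abs(cv(bi, b(pair_2[1]))) + abs(cv(bj, b(pair_2[2])))
  list(zygote_msv = zmsv, similarity = sim)
}
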