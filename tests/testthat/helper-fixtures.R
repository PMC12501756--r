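# Fixtures built in code: the two-parent worked example and random small
# instances (phased genotypes + map + effects) for property-style tests.

table1 <- worked_example()

# Random instance: L markers over n_chrom chromosomes, n_parents phased
# individuals with independent haplotypes, n_traits effect rows.
random_instance <- function(L = 8, n_chrom = 1, n_parents = 2, n_traits = 1,
                            maxlen = 1) {
  chrom <- sort(sample(paste0("c", seq_len(n_chrom)), L, replace = TRUE))
  pos <- unlist(lapply(unique(chrom), function(cc)
    sort(runif(sum(chrom == cc), 0, maxlen))))
  mk <- paste0("m", seq_len(L))
  map <- genetic_map(chrom, mk, pos_morgan = pos)
  h1 <- matrix(rbinom(n_parents * L, 1, 0.5), n_parents, L,
               dimnames = list(paste0("p", seq_len(n_parents)), mk))
  h2 <- matrix(rbinom(n_parents * L, 1, 0.5), n_parents, L,
               dimnames = list(paste0("p", seq_len(n_parents)), mk))
  pg <- phased_genotypes(h1, h2)
  eff <- marker_effects(matrix(rnorm(n_traits * L), n_traits, L),
                        markers = mk)
  list(pg = pg, map = map, effects = eff)
}

# Swap the two haplotypes of one parent on one chromosome.
flip_haplotypes <- function(pg, parent, map, chrom) {
  k <- map$chrom == chrom
  tmp <- pg$h1[parent, k]
  pg$h1[parent, k] <- pg$h2[parent, k]
  pg$h2[parent, k] <- tmp
  pg
}

# Single-chromosome oracle MSV/covariance for possibly multi-chromosome
# instances: enumerate each chromosome separately and add the moments.
oracle_by_chrom <- function(inst) {
  chroms <- unique(inst$map$chrom)
  var_tot <- NULL
  cov_tot <- NULL
  for (cc in chroms) {
    k <- inst$map$chrom == cc
    theta <- haldane_inv(diff(inst$map$pos[k]))
    pgc <- phased_genotypes(inst$pg$h1[, k, drop = FALSE],
                            inst$pg$h2[, k, drop = FALSE])
    pat <- enumerate_patterns(theta, pgc, unclass(inst$effects)[1, k])
    mom <- oracle_moments(pat)
    if (is.null(var_tot)) {
      var_tot <- mom$var
      cov_tot <- abs(mom$cov)
    } else {
      var_tot <- var_tot + mom$var
      cov_tot <- cov_tot + abs(mom$cov)
    }
  }
  list(var = var_tot, cov = cov_tot)
}
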