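## Self-contained stochastic breeding-program simulator: base population with
## burn-in LD, trait architecture, meiosis under the Haldane model, the
## truncation / contribution-selection scheme grid, and the monitored
## diversity parameters.

#' Simulation configuration
#'
#' Defaults mirror the reference breeding-program design: 1000 individuals
#' (even sex split), 10 chromosomes of 1 Morgan with 1000 SNPs and 200 QTLs
#' each, additive QTL effects from Normal(0, 100), heritability 0.25, top 1%
#' of males and 50% of females selected under truncation, 4 offspring per
#' mating, at most 50 females per male and at least 5 sires. Founder allele
#' frequencies are drawn from a U-shaped Beta(0.5, 0.5) and map-consistent LD
#' is established by random-mating burn-in generations. [desk_config()] is a
#' reduced preset that preserves the 5-sire truncation structure at 1/5 the
#' population size.
#'
#' @param n_ind population size (even; half males, half females).
#' @param n_chrom number of chromosomes.
#' @param chrom_len chromosome length in Morgans.
#' @param snp_per_chrom,qtl_per_chrom neutral and trait loci per chromosome.
#' @param qtl_sd standard deviation of additive QTL effects.
#' @param h2 trait heritability (recorded; selection uses true breeding
#'   values under the known-effects assumption).
#' @param n_gen selection generations.
#' @param n_rep replicates.
#' @param burn_in random-mating generations establishing base LD.
#' @param founder_beta shape parameters of the founder allele-frequency Beta.
#' @param scheme one of `"TS-BV"`, `"TS-Index"`, `"MOCS-S"`, `"MOCS-K"`,
#'   `"OCS-GRM"`.
#' @param criterion selection criterion for MOCS/OCS schemes
#'   (`"BV"` or `"Index"`).
#' @param constraint_percentile base-population similarity percentile fixing
#'   the MOCS constraint (held constant across generations).
#' @param delta_f per-generation inbreeding-rate target for `"OCS-GRM"`.
#' @param prop_males,prop_females selected proportions under truncation.
#' @param offspring_per_mating offspring per mating (sexes alternate).
#' @param max_per_male cap on females mated to one male.
#' @param min_sires minimum number of distinct sires.
#' @param max_sires optional maximum number of sires (iterative adaptation).
#' @param matrix_markers markers used for similarity matrices: `"qtl"`
#'   (trait loci, the known-effects default) or `"all"`.
#' @param infeasible_action on an infeasible contribution program:
#'   `"min_similarity"` (use the most diverse feasible-bounds solution,
#'   logged) or `"abort"`.
#' @param seed master seed; each replicate derives an independent stream.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_ind = 1000, n_chrom = 10, chrom_len = 1,
                       snp_per_chrom = 1000, qtl_per_chrom = 200,
                       qtl_sd = 10, h2 = 0.25, n_gen = 50, n_rep = 100,
                       burn_in = 10, founder_beta = c(0.5, 0.5),
                       scheme = "TS-BV", criterion = c("BV", "Index"),
                       constraint_percentile = 20, delta_f = 0.01,
                       prop_males = 0.01, prop_females = 0.5,
                       offspring_per_mating = 4, max_per_male = 50,
                       min_sires = 5, max_sires = NULL,
                       matrix_markers = c("qtl", "all"),
                       infeasible_action = c("min_similarity", "abort"),
                       seed = 1) {
  criterion <- match.arg(criterion)
  matrix_markers <- match.arg(matrix_markers)
  infeasible_action <- match.arg(infeasible_action)
  scheme <- match.arg(scheme, c("TS-BV", "TS-Index", "MOCS-S", "MOCS-K", "OCS-GRM"))
  stopifnot(n_ind >= 4, n_ind %% 2 == 0, n_chrom >= 1, snp_per_chrom >= 1,
            qtl_per_chrom >= 1, n_gen >= 1, n_rep >= 1, burn_in >= 0,
            h2 > 0, h2 <= 1, prop_males > 0, prop_males <= 1,
            prop_females > 0, prop_females <= 1, offspring_per_mating >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' @rdname sim_config
#' @param ... overrides passed on to [sim_config()].
#' @export
desk_config <- function(...) {
  defaults <- list(n_ind = 200, n_chrom = 3, snp_per_chrom = 100,
                   qtl_per_chrom = 20, n_gen = 15, n_rep = 30,
                   prop_males = 0.05, max_per_male = 10, min_sires = 5)
  args <- list(...)
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' Sample gametes under the Haldane model
#'
#' Draws one gamete per requested meiosis. The crossover process has no
#' interference (Poisson crossovers along the chromosome), so at marker
#' resolution the transmitted haplotype follows a Markov chain: the starting
#' haplotype is Bernoulli(1/2) and the source switches between adjacent
#' markers independently with probability `theta = haldane_inv(d)`.
#'
#' @param pg a [phased_genotypes()] object holding the parents.
#' @param parents vector of parent ids, one per gamete (repeats allowed).
#' @param map the [genetic_map()] aligned with `pg`.
#' @return integer matrix, gametes x markers (0/1 alleles).
#' @export
sample_gametes <- function(pg, parents, map) {
  check_aligned(pg, map = map)
  n_g <- length(parents)
  L <- ncol(pg$h1)
  out <- matrix(0L, n_g, L, dimnames = list(NULL, colnames(pg$h1)))
  H1 <- pg$h1[parents, , drop = FALSE]
  H2 <- pg$h2[parents, , drop = FALSE]
  for (k_idx in chrom_index(map)) {
    Lc <- length(k_idx)
    theta <- haldane_inv(diff(map$pos[k_idx]))
    src <- matrix(0L, n_g, Lc)
    cur <- rbinom(n_g, 1L, 0.5)
    src[, 1] <- cur
    if (Lc > 1) for (k in 2:Lc) {
      cur <- (cur + rbinom(n_g, 1L, theta[k - 1])) %% 2L
      src[, k] <- cur
    }
    out[, k_idx] <- H1[, k_idx, drop = FALSE] * (1L - src) +
      H2[, k_idx, drop = FALSE] * src
  }
  out
}

#' @rdname sample_gametes
#' @param parent single parent id.
#' @return `meiosis()`: integer vector of length markers.
#' @export
meiosis <- function(pg, parent, map) drop(sample_gametes(pg, parent, map))

#' Founder population with burn-in LD
#'
#' Draws founder haplotypes marker-wise with allele frequencies from the
#' configured Beta distribution, then runs random-mating burn-in generations
#' through [sample_gametes()] to establish map-consistent linkage
#' disequilibrium. Deterministic for a given seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return object of class `population_state`: list with `pg`
#'   ([phased_genotypes()] with sex), `map`, `qtl` (logical per marker),
#'   `effects` ([marker_effects()], zero at SNPs), `generation`.
#' @export
make_base_population <- function(config, seed = config$seed) {
  set.seed(seed)
  nm_chrom <- config$snp_per_chrom + config$qtl_per_chrom
  chrom <- rep(paste0("chr", seq_len(config$n_chrom)), each = nm_chrom)
  pos <- unlist(lapply(seq_len(config$n_chrom), function(cc)
    sort(runif(nm_chrom, 0, config$chrom_len))))
  marker <- paste0(chrom, "_m", sequence(rep(nm_chrom, config$n_chrom)))
  map <- genetic_map(chrom, marker, pos_morgan = pos)
  qtl <- as.logical(unlist(lapply(seq_len(config$n_chrom), function(cc) {
    f <- rep(FALSE, nm_chrom)
    f[sample.int(nm_chrom, config$qtl_per_chrom)] <- TRUE
    f
  })))
  L <- nrow(map)
  p <- rbeta(L, config$founder_beta[1], config$founder_beta[2])
  n <- config$n_ind
  h1 <- matrix(rbinom(n * L, 1L, rep(p, each = n)), n, L)
  h2 <- matrix(rbinom(n * L, 1L, rep(p, each = n)), n, L)
  dimnames(h1) <- dimnames(h2) <- list(paste0("f", seq_len(n)), marker)
  sex <- rep(c("M", "F"), length.out = n)
  pg <- phased_genotypes(h1, h2, sex = sex)
  eff <- numeric(L)
  eff[qtl] <- rnorm(sum(qtl), 0, config$qtl_sd)
  effects <- marker_effects(matrix(eff, 1, L), traits = "trait",
                            markers = marker)
  for (g in seq_len(config$burn_in)) {
    males <- individuals(pg)[pg$sex == "M"]
    females <- individuals(pg)[pg$sex == "F"]
    sires <- sample(males, n, replace = TRUE)
    dams <- sample(females, n, replace = TRUE)
    h1 <- sample_gametes(pg, sires, map)
    h2 <- sample_gametes(pg, dams, map)
    rownames(h1) <- rownames(h2) <- paste0("b", g, "_", seq_len(n))
    pg <- phased_genotypes(h1, h2, sex = rep(c("M", "F"), length.out = n))
  }
  structure(list(pg = pg, map = map, qtl = qtl, effects = effects,
                 generation = 0L),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat("population_state: generation", x$generation, "-",
      nrow(x$pg$h1), "individuals,", ncol(x$pg$h1), "markers (",
      sum(x$qtl), "QTL )\n")
  invisible(x)
}

#' True breeding values of a population state
#' @param pop a `population_state`.
#' @return named numeric vector (QTL effects summed per individual).
#' @export
true_bv <- function(pop) {
  drop(breeding_value(pop$pg, pop$effects))
}

#' Monitor diversity and gain statistics
#'
#' One record per call: genetic gain in base-generation genetic-SD units, the
#' SD of true breeding values, genomic inbreeding `F = 1 - Ho` (mean observed
#' SNP heterozygosity), the count of favourable QTL alleles lost (the allele
#' whose substitution effect is positive, at frequency exactly zero), the
#' mean favourable QTL allele frequency, and the count of SNP loci with an
#' allele lost (fixed loci).
#'
#' @param pop a `population_state`.
#' @param base_stats list with `mean` and `sd` of base-generation true
#'   breeding values.
#' @param n_sires number of distinct sires that produced this generation
#'   (`NA` for the base generation).
#' @param feasible logical: was the contribution program feasible.
#' @return one-row data.frame.
#' @export
monitor_population <- function(pop, base_stats, n_sires = NA_integer_,
                               feasible = TRUE) {
  bv <- true_bv(pop)
  dos <- pop$pg$h1 + pop$pg$h2
  p <- colMeans(dos) / 2
  het <- colMeans(pop$pg$h1 != pop$pg$h2)
  snp <- !pop$qtl
  eff <- drop(unclass(pop$effects))
  qtl_k <- which(pop$qtl & eff != 0)
  fav_freq <- ifelse(eff[qtl_k] > 0, p[qtl_k], 1 - p[qtl_k])
  data.frame(
    generation = pop$generation,
    gain = (mean(bv) - base_stats$mean) / base_stats$sd,
    sd_bv = sd(bv),
    inbreeding = 1 - mean(het[snp]),
    qtl_lost = sum(fav_freq == 0),
    fav_freq = mean(fav_freq),
    snp_lost = sum(p[snp] == 0 | p[snp] == 1),
    n_sires = n_sires,
    feasible = feasible)
}

## Criterion per individual under a scheme ("BV" or "Index").
sim_criterion <- function(pop, criterion, prop_males, R_list_sub, sub) {
  b <- true_bv(pop)
  if (criterion == "BV") return(b)
  msv <- population_msv(sub$pg, sub$effects, sub$map, R_list = R_list_sub)
  selection_index(b, pmax(msv, 0), prop_males)
}

## Restrict a population to the markers used for similarity matrices.
subset_markers <- function(pop, keep) {
  pg <- phased_genotypes(pop$pg$h1[, keep, drop = FALSE],
                         pop$pg$h2[, keep, drop = FALSE], sex = pop$pg$sex)
  map <- pop$map[keep, ]
  class(map) <- c("genetic_map", "data.frame")
  eff <- marker_effects(unclass(pop$effects)[, keep, drop = FALSE],
                        markers = map$marker)
  list(pg = pg, map = map, effects = eff)
}

#' Run a selection scheme
#'
#' Simulates the configured scheme over all replicates: base population,
#' per-generation selection (truncation or contribution optimisation),
#' mating allocation, meiosis, and monitoring. The contribution constraint is
#' calibrated once from the base population and held fixed; for `"OCS-GRM"`
#' the coancestry bound follows the standard per-generation recursion
#' `C_t = C_{t-1} + delta_f * (1 - C_{t-1})` from the base mean coancestry.
#' Offspring sexes alternate so the sex ratio stays even; population size is
#' constant.
#'
#' @param config a [sim_config()].
#' @return data.frame of monitor records: one row per replicate x generation
#'   (generation 0 = base), with a `scheme` column.
#' @export
run_scheme <- function(config) {
  out <- vector("list", config$n_rep)
  for (rep_i in seq_len(config$n_rep)) {
    rep_seed <- (config$seed * 10007L + rep_i * 101L) %% 2147483647L
    out[[rep_i]] <- run_replicate(config, rep_seed, rep_i)
  }
  res <- do.call(rbind, out)
  res$scheme <- config$scheme
  rownames(res) <- NULL
  res
}

run_replicate <- function(config, rep_seed, rep_i) {
  pop <- make_base_population(config, rep_seed)
  bv0 <- true_bv(pop)
  base_stats <- list(mean = mean(bv0), sd = sd(bv0))
  n <- config$n_ind
  rule <- if (startsWith(config$scheme, "TS")) "TS"
          else if (config$scheme == "OCS-GRM") "OCS" else "MOCS"
  criterion <- switch(config$scheme, `TS-BV` = "BV", `TS-Index` = "Index",
                      config$criterion)
  keep <- if (config$matrix_markers == "qtl") pop$qtl else rep(TRUE, ncol(pop$pg$h1))

  calib <- NULL; cbar <- NULL
  if (rule == "MOCS") {
    sub <- subset_markers(pop, keep)
    Rl <- build_R_list(sub$map)
    S0 <- build_S(sub$pg, sub$effects, sub$map, R_list = Rl)
    if (config$scheme == "MOCS-K") {
      K0 <- suppressWarnings(standardize_similarity(S0))
      calib <- calibrate_constraint(K0, config$constraint_percentile, "none")
    } else {
      calib <- calibrate_constraint(S0, config$constraint_percentile, "max")
    }
  } else if (rule == "OCS") {
    cbar <- mean(vanraden_grm(pop$pg)) / 2
  }

  records <- vector("list", config$n_gen + 1L)
  records[[1]] <- cbind(replicate = rep_i,
                        monitor_population(pop, base_stats))
  for (gen in seq_len(config$n_gen)) {
    sub <- subset_markers(pop, keep)
    Rl <- build_R_list(sub$map)
    crit <- sim_criterion(pop, criterion, config$prop_males, Rl, sub)
    ids <- individuals(pop$pg)
    males <- ids[pop$pg$sex == "M"]
    females <- ids[pop$pg$sex == "F"]
    n_f_sel <- max(1L, round(config$prop_females * length(females)))
    sel_f <- females[order(-crit[females], females)][seq_len(n_f_sel)]
    feasible <- TRUE

    if (rule == "TS") {
      n_m_sel <- max(1L, round(config$prop_males * length(males)))
      sel_m <- males[order(-crit[males], males)][seq_len(n_m_sel)]
      contrib <- setNames(rep(1 / (2 * n_m_sel), n_m_sel), sel_m)
    } else {
      cand <- c(males, sel_f)
      if (rule == "MOCS") {
        Sg <- unclass(build_S(sub$pg, sub$effects, sub$map, R_list = Rl))[cand, cand]
        if (config$scheme == "MOCS-K") {
          zero <- cand[diag(Sg) <= 1e-12]
          if (length(zero)) { # no Mendelian sampling information: exclude
            cand <- setdiff(cand, zero)
            sel_f <- setdiff(sel_f, zero)
            Sg <- Sg[cand, cand]
          }
          Q <- Sg / sqrt(outer(diag(Sg), diag(Sg)))
          diag(Q) <- 1
          qbar <- calib$qbar
        } else {
          Q <- unclass(Sg) / max(unclass(Sg))
          qbar <- calib$qbar
        }
      } else {
        cbar <- cbar + config$delta_f * (1 - cbar)
        Q <- vanraden_grm(pop$pg)[cand, cand]
        qbar <- cbar
      }
      sexv <- ifelse(cand %in% males, "M", "F")
      Ff <- length(sel_f)
      lb <- ifelse(sexv == "F", 1 / (2 * Ff), 0)
      ub <- ifelse(sexv == "F", 1 / (2 * Ff), config$max_per_male / (2 * Ff))
      prob <- contribution_problem(setNames(crit[cand], cand), Q, qbar, sexv,
                                   lb = lb, ub = ub,
                                   kind = if (rule == "OCS") "GRM"
                                          else if (config$scheme == "MOCS-K") "K" else "S")
      sol <- solve_contributions(prob, min_males = config$min_sires,
                                 max_males = config$max_sires,
                                 floor_contribution = 1 / (2 * Ff),
                                 support_eps = 1 / (4 * Ff),
                                 gap_tol = 1e-9)
      if (sol$status != "optimal") {
        feasible <- FALSE
        if (config$infeasible_action == "abort") {
          res <- do.call(rbind, records[seq_len(gen)])
          attr(res, "aborted") <- TRUE
          return(res)
        }
      }
      nm <- sol$n[cand[sexv == "M"]]
      nm <- nm[nm > 1 / (8 * Ff)]   # below a quarter mating: not used
      if (length(nm) < 1) { # degenerate fallback: truncation on the criterion
        mm <- males[order(-crit[males], males)][seq_len(config$min_sires)]
        nm <- setNames(rep(1 / (2 * config$min_sires), length(mm)), mm)
      }
      contrib <- nm
    }

    mate_seed <- sample.int(2147483646L, 1L)
    ## the sire-count minimum is enforced by the optimiser's floor (or the
    ## truncation proportion); the allocator only rounds and caps here
    matings <- allocate_matings(contrib, sel_f,
                                max_per_male = config$max_per_male,
                                min_males = 1L, seed = mate_seed)
    k <- config$offspring_per_mating
    sires <- rep(matings$sire, each = k)
    dams <- rep(matings$dam, each = k)
    h1 <- sample_gametes(pop$pg, sires, pop$map)
    h2 <- sample_gametes(pop$pg, dams, pop$map)
    rownames(h1) <- rownames(h2) <- paste0("g", gen, "_", seq_along(sires))
    pg <- phased_genotypes(h1, h2, sex = rep(c("M", "F"), length.out = length(sires)))
    pop <- structure(list(pg = pg, map = pop$map, qtl = pop$qtl,
                          effects = pop$effects, generation = gen),
                     class = "population_state")
    records[[gen + 1L]] <- cbind(replicate = rep_i,
                                 monitor_population(pop, base_stats,
                                                    n_sires = length(unique(matings$sire)),
                                                    feasible = feasible))
  }
  do.call(rbind, records)
}
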