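## Core data types: genetic map, phased genotypes, marker effects, and the
## constructions every other module consumes (R matrices, genotype/phase
## indicators, signed effect vectors, breeding values).

#' Haldane map function and its inverse
#'
#' Convert a recombination fraction to a map distance in Morgans under the
#' Haldane (no-interference) model, `d = -0.5 * log(1 - 2 * theta)`, and back,
#' `theta = (1 - exp(-2 * d)) / 2`.
#'
#' @param theta recombination fraction(s) in `[0, 0.5)`.
#' @param d map distance(s) in Morgans, `>= 0`.
#' @return numeric vector of distances (Morgans) or recombination fractions.
#' @examples
#' haldane(0.1)            # ~0.1115718
#' haldane_inv(haldane(0.1))
#' @export
haldane <- function(theta) {
  if (any(!is.finite(theta)) || any(theta < 0) || any(theta >= 0.5))
    stop("recombination fractions must lie in [0, 0.5)")
  -0.5 * log(1 - 2 * theta)
}

#' @rdname haldane
#' @export
haldane_inv <- function(d) {
  if (any(!is.finite(d) & !is.infinite(d)) || any(d < 0))
    stop("map distances must be >= 0")
  (1 - exp(-2 * d)) / 2
}

#' Genetic map
#'
#' A per-marker table of chromosome, marker id and position in Morgans.
#' Positions must be non-decreasing within each chromosome and marker ids
#' unique. Co-located markers (zero distance, distinct loci) are allowed and
#' flagged with a warning, since real genotyping chips contain them.
#'
#' @param chrom chromosome id per marker (coerced to character).
#' @param marker marker id per marker (unique).
#' @param pos_morgan position in Morgans; exactly one of `pos_morgan`/`pos_cm`.
#' @param pos_cm position in centimorgans (divided by 100 on read).
#' @return object of class `genetic_map`: a data.frame with columns
#'   `chrom`, `marker`, `pos` (Morgans).
#' @export
genetic_map <- function(chrom, marker, pos_morgan = NULL, pos_cm = NULL) {
  if (is.null(pos_morgan) == is.null(pos_cm))
    stop("supply exactly one of pos_morgan or pos_cm")
  pos <- if (is.null(pos_morgan)) as.numeric(pos_cm) / 100 else as.numeric(pos_morgan)
  chrom <- as.character(chrom)
  marker <- as.character(marker)
  if (length(chrom) != length(pos) || length(marker) != length(pos))
    stop("chrom, marker and positions must have equal length")
  if (any(!is.finite(pos))) stop("all map positions must be finite")
  if (anyDuplicated(marker)) stop("marker ids must be unique")
  for (cc in unique(chrom)) {
    p <- pos[chrom == cc]
    if (is.unsorted(p)) stop("positions must be non-decreasing within chromosome ", cc)
    if (anyDuplicated(p))
      warning("chromosome ", cc, " contains co-located markers (d = 0); ",
              "their within-family covariance is 0.25", call. = FALSE)
  }
  structure(data.frame(chrom = chrom, marker = marker, pos = pos,
                       stringsAsFactors = FALSE),
            class = c("genetic_map", "data.frame"))
}

#' Build a genetic map from adjacent recombination fractions
#'
#' Converts recombination fractions between adjacent markers (the worked
#' example's input style) to cumulative Morgan positions via [haldane()], so
#' that fraction-based and position-based inputs share one code path.
#'
#' @param theta recombination fractions between adjacent markers (length L-1).
#' @param chrom single chromosome id.
#' @param markers optional marker ids (default `m1..mL`).
#' @return a [genetic_map()].
#' @export
map_from_theta <- function(theta, chrom = "1", markers = NULL) {
  L <- length(theta) + 1L
  if (is.null(markers)) markers <- paste0("m", seq_len(L))
  genetic_map(rep(chrom, L), markers, pos_morgan = c(0, cumsum(haldane(theta))))
}

#' Phased genotypes
#'
#' Two haplotype allele sequences per individual over biallelic markers,
#' coded 1 = reference allele, 0 = alternate. Derived quantities are the
#' genotype indicator `c = h1 + h2 - 1` (1 homozygous reference,
#' 0 heterozygous, -1 homozygous alternate) and the phase indicator
#' `delta = h1 - h2` (1 reference on first haplotype, -1 on second,
#' 0 homozygous).
#'
#' @param h1,h2 integer/numeric matrices (individuals x markers) with entries
#'   in `{0, 1}`; rownames are individual ids, colnames marker ids.
#' @param sex optional per-individual sex labels, `"M"`/`"F"` (or `NA`).
#' @return object of class `phased_genotypes`.
#' @export
phased_genotypes <- function(h1, h2, sex = NULL) {
  h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  storage.mode(h1) <- "integer"; storage.mode(h2) <- "integer"
  if (!identical(dim(h1), dim(h2))) stop("h1 and h2 must have identical dimensions")
  if (any(is.na(h1)) || any(is.na(h2)) ||
      !all(h1 %in% c(0L, 1L)) || !all(h2 %in% c(0L, 1L)))
    stop("haplotype alleles must be complete and coded 0/1 (1 = reference)")
  if (is.null(rownames(h1))) rownames(h1) <- rownames(h2) <- paste0("ind", seq_len(nrow(h1)))
  if (is.null(colnames(h1))) colnames(h1) <- colnames(h2) <- paste0("m", seq_len(ncol(h1)))
  rownames(h2) <- rownames(h1); colnames(h2) <- colnames(h1)
  if (!is.null(sex)) {
    sex <- as.character(sex)
    if (length(sex) != nrow(h1)) stop("sex must have one entry per individual")
    if (!all(sex %in% c("M", "F") | is.na(sex))) stop('sex labels must be "M", "F" or NA')
  }
  structure(list(h1 = h1, h2 = h2, sex = sex), class = "phased_genotypes")
}

#' @export
print.phased_genotypes <- function(x, ...) {
  cat("phased_genotypes:", nrow(x$h1), "individuals x", ncol(x$h1), "markers\n")
  invisible(x)
}

#' @export
dim.phased_genotypes <- function(x) dim(x$h1)

#' Individual ids of a phased genotype set
#' @param pg a [phased_genotypes()] object.
#' @return character vector of individual ids.
#' @export
individuals <- function(pg) rownames(pg$h1)

#' Genotype and phase indicators
#'
#' `geno_indicator` returns the matrix of genotype indicators
#' `c = h1 + h2 - 1` in `{1, 0, -1}`; `phase_indicator` the phase indicators
#' `delta = h1 - h2` in `{1, 0, -1}`. `delta != 0` exactly where `c == 0`.
#'
#' @param pg a [phased_genotypes()] object.
#' @return integer matrix, individuals x markers.
#' @export
geno_indicator <- function(pg) pg$h1 + pg$h2 - 1L

#' @rdname geno_indicator
#' @export
phase_indicator <- function(pg) pg$h1 - pg$h2

#' Additive marker effects
#'
#' A traits x markers matrix of additive (allele substitution) effects in
#' trait units per copy of the reference allele, with optional economic index
#' weights (one per trait).
#'
#' @param effects numeric matrix (traits x markers) or vector (single trait).
#' @param traits optional trait names.
#' @param markers optional marker ids.
#' @param weights optional numeric index weights, one per trait.
#' @return object of class `marker_effects` (a matrix with a `weights`
#'   attribute).
#' @export
marker_effects <- function(effects, traits = NULL, markers = NULL, weights = NULL) {
  if (is.null(dim(effects))) effects <- matrix(effects, nrow = 1)
  effects <- as.matrix(effects)
  if (any(!is.finite(effects))) stop("all marker effects must be finite")
  if (!is.null(traits)) rownames(effects) <- traits
  if (is.null(rownames(effects))) rownames(effects) <- paste0("trait", seq_len(nrow(effects)))
  if (!is.null(markers)) colnames(effects) <- markers
  if (is.null(colnames(effects))) colnames(effects) <- paste0("m", seq_len(ncol(effects)))
  if (!is.null(weights)) {
    if (length(weights) != nrow(effects))
      stop("index weights must have one entry per trait")
    if (any(!is.finite(weights))) stop("index weights must be finite")
  }
  structure(effects, weights = weights, class = c("marker_effects", "matrix", "array"))
}

#' Index weights stored with a `marker_effects` object
#' @param effects a [marker_effects()] object.
#' @return numeric vector of weights or `NULL`.
#' @export
index_weights <- function(effects) attr(effects, "weights")

## Alignment guard: genotypes, effects and map must describe the same markers
## in the same order.
check_aligned <- function(pg, effects = NULL, map = NULL) {
  mk <- colnames(pg$h1)
  if (!is.null(effects) && !identical(colnames(unclass(effects)), mk))
    stop("marker ids of effects do not align with genotypes")
  if (!is.null(map) && !identical(map$marker, mk))
    stop("marker ids of map do not align with genotypes")
  invisible(TRUE)
}

#' Within-family LD covariance matrix R for one chromosome
#'
#' The expected within-family covariance of transmitted-allele indicators:
#' `rho_kl = exp(-2 * d_kl) / 4` with `d_kl` the absolute map distance in
#' Morgans. The diagonal is exactly 0.25; markers on different chromosomes
#' have zero covariance, so R is block-diagonal and only the requested
#' chromosome block is materialised. This all-positive matrix is built once
#' per chromosome and shared across all parents and traits.
#'
#' @param map a [genetic_map()].
#' @param chrom chromosome id present in `map`.
#' @return symmetric numeric matrix (markers on `chrom` squared), entries in
#'   `(0, 0.25]`.
#' @export
build_R <- function(map, chrom) {
  idx <- map$chrom == as.character(chrom)
  if (!any(idx)) stop("chromosome ", chrom, " not present in map (or empty)")
  p <- map$pos[idx]
  R <- exp(-2 * abs(outer(p, p, "-"))) / 4
  dimnames(R) <- list(map$marker[idx], map$marker[idx])
  R
}

#' Per-chromosome list of R matrices
#'
#' Builds the R block for every chromosome of the map once; the list is the
#' shared cache reused across parents, traits and pairs.
#'
#' @param map a [genetic_map()].
#' @return named list of matrices, one per chromosome (map order).
#' @export
build_R_list <- function(map) {
  chroms <- unique(map$chrom)
  setNames(lapply(chroms, function(cc) build_R(map, cc)), chroms)
}

## Split marker indices by chromosome, in map order.
chrom_index <- function(map) {
  chroms <- unique(map$chrom)
  setNames(lapply(chroms, function(cc) which(map$chrom == cc)), chroms)
}

#' Parent-specific signed marker effects
#'
#' Transforms population marker effects `m_k` into the parent-specific vector
#' `m_ik = delta_ik * m_k` (one row per trait): the effect keeps its sign if
#' the reference allele sits on the parent's first haplotype, flips sign if
#' on the second, and is zeroed at homozygous loci. Swapping the parent's
#' haplotypes negates the whole vector, which leaves all MSVs and (absolute)
#' similarities unchanged.
#'
#' @param pg a [phased_genotypes()] object.
#' @param effects a [marker_effects()] object aligned with `pg`.
#' @param parent individual id (or row index) of the parent.
#' @return object of class `signed_effects`: list with `parent` and `M`
#'   (traits x markers matrix).
#' @export
signed_effects <- function(pg, effects, parent) {
  check_aligned(pg, effects = effects)
  if (is.character(parent)) {
    if (!parent %in% individuals(pg)) stop("parent ", parent, " not found")
  } else parent <- individuals(pg)[parent]
  delta <- pg$h1[parent, ] - pg$h2[parent, ]
  M <- sweep(unclass(effects), 2, delta, "*")
  structure(list(parent = parent, M = M), class = "signed_effects")
}

#' @export
print.signed_effects <- function(x, ...) {
  cat("signed_effects for", x$parent, "-", nrow(x$M), "trait(s) x",
      ncol(x$M), "markers\n")
  invisible(x)
}

#' Breeding value of an individual
#'
#' `b_i = c_i' m` per trait: the inner product of the genotype indicator
#' vector (1/0/-1) with the additive marker effects.
#'
#' @inheritParams signed_effects
#' @param parent individual id(s); default all individuals.
#' @return numeric matrix, individuals x traits.
#' @export
breeding_value <- function(pg, effects, parent = individuals(pg)) {
  check_aligned(pg, effects = effects)
  ci <- geno_indicator(pg)[parent, , drop = FALSE]
  ci %*% t(unclass(effects))
}
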