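## Readers and writers for the standard formats (phased VCF, PLINK .map,
## delimited effects/haplotype/matrix tables) and the worked-example fixture
## generator. All text formats; writers emit a "#" comment header that
## readers skip.

header_comment <- function(seed = NULL) {
  paste0("# hapsel ", as.character(utils::packageVersion("hapsel")),
         if (!is.null(seed)) paste0(" seed=", seed), " ", format(Sys.time(), "%Y-%m-%d"))
}

#' Read a PLINK-style genetic map
#'
#' Four whitespace-separated columns: chromosome, marker id, position in cM
#' (authoritative; divided by 100 to Morgans) and bp (retained only as
#' metadata). Positions must be non-decreasing within each chromosome.
#'
#' @param path path to the `.map` file.
#' @return a [genetic_map()].
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("map file needs columns: chrom, marker, cM[, bp]")
  genetic_map(tab[[1]], tab[[2]], pos_cm = as.numeric(tab[[3]]))
}

#' Write a PLINK-style genetic map
#' @param map a [genetic_map()].
#' @param path output path.
#' @export
write_map <- function(map, path) {
  writeLines(header_comment(), path)
  tab <- data.frame(chrom = map$chrom, marker = map$marker,
                    cm = map$pos * 100, bp = 0L)
  write.table(tab, path, append = TRUE, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' Read a marker-effects table
#'
#' Tab-separated with header `marker<TAB>trait1[<TAB>trait2 ...]`, one row
#' per marker. Marker ids are cross-validated against `map` when given.
#'
#' @param path path to the effects file.
#' @param map optional [genetic_map()] for id validation and ordering.
#' @return a [marker_effects()].
#' @export
read_effects <- function(path, map = NULL) {
  if (!file.exists(path)) stop("effects file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2) stop("effects file needs a marker column and >= 1 trait column")
  if (any(!vapply(tab[-1], is.numeric, TRUE))) stop("empty or non-numeric effects column")
  mk <- as.character(tab[[1]])
  E <- t(as.matrix(tab[-1]))
  colnames(E) <- mk
  if (!is.null(map)) {
    missing <- setdiff(map$marker, mk)
    extra <- setdiff(mk, map$marker)
    if (length(missing) || length(extra))
      stop("effects/map marker mismatch; missing: ",
           paste(head(missing, 5), collapse = ","), " extra: ",
           paste(head(extra, 5), collapse = ","))
    E <- E[, map$marker, drop = FALSE]
  }
  marker_effects(E, traits = rownames(E))
}

#' Write a marker-effects table
#' @param effects a [marker_effects()].
#' @param path output path.
#' @export
write_effects <- function(effects, path) {
  E <- unclass(effects)
  tab <- data.frame(marker = colnames(E), t(E), check.names = FALSE)
  writeLines(header_comment(), path)
  suppressWarnings(write.table(tab, path, append = TRUE, sep = "\t",
                               quote = FALSE, row.names = FALSE))
}

#' Read phased genotypes from a haplotype table
#'
#' Tab-separated with header `id<TAB>sex<TAB>hap<TAB><marker ids...>`: two
#' rows per individual (`hap` 1 and 2), alleles coded `1` (reference) or `2`
#' (alternate) as in the worked-example notation. Missing or malformed
#' alleles are rejected with coordinates.
#'
#' @param path path to the haplotype table.
#' @param map optional [genetic_map()]; marker order is taken from it.
#' @return a [phased_genotypes()].
#' @export
read_haplotypes <- function(path, map = NULL) {
  if (!file.exists(path)) stop("haplotype file not found: ", path)
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("id", "sex", "hap")
  if (!all(need %in% names(tab)[1:3]))
    stop("haplotype table must start with columns id, sex, hap")
  mk <- names(tab)[-(1:3)]
  A <- matrix(suppressWarnings(as.numeric(as.matrix(tab[-(1:3)]))),
              nrow = nrow(tab), dimnames = list(NULL, mk))
  bad <- which(is.na(A) | !(A == 1 | A == 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid allele at individual ", tab$id[bad[1, 1]], ", marker ",
         mk[bad[1, 2]], " (alleles must be 1 = reference or 2 = alternate)")
  ids <- unique(tab$id)
  h <- function(w) {
    rows <- tab$hap == w
    m <- 2 - A[rows, , drop = FALSE]
    rownames(m) <- tab$id[rows]
    m[ids, , drop = FALSE]
  }
  if (!all(table(tab$id) == 2) || !all(sort(unique(tab$hap)) == c(1, 2)))
    stop("each individual needs exactly one row per haplotype (hap 1 and 2)")
  sex <- tab$sex[match(ids, tab$id)]
  sex[sex %in% c("", "NA")] <- NA
  pg <- phased_genotypes(h(1), h(2), sex = if (all(is.na(sex))) NULL else sex)
  if (!is.null(map)) {
    if (!setequal(map$marker, colnames(pg$h1)))
      stop("haplotype/map marker mismatch")
    pg$h1 <- pg$h1[, map$marker, drop = FALSE]
    pg$h2 <- pg$h2[, map$marker, drop = FALSE]
  }
  pg
}

#' Write phased genotypes as a haplotype table
#' @param pg a [phased_genotypes()].
#' @param path output path.
#' @export
write_haplotypes <- function(pg, path) {
  ids <- individuals(pg)
  sex <- if (is.null(pg$sex)) rep(NA, length(ids)) else pg$sex
  rows <- lapply(seq_along(ids), function(i) {
    rbind(data.frame(id = ids[i], sex = sex[i], hap = 1,
                     t(2 - pg$h1[i, ]), check.names = FALSE),
          data.frame(id = ids[i], sex = sex[i], hap = 2,
                     t(2 - pg$h2[i, ]), check.names = FALSE))
  })
  tab <- do.call(rbind, rows)
  colnames(tab)[-(1:3)] <- colnames(pg$h1)
  writeLines(header_comment(), path)
  suppressWarnings(write.table(tab, path, append = TRUE, sep = "\t",
                               quote = FALSE, row.names = FALSE))
}

#' Read phased genotypes from a VCF
#'
#' Accepts only fully phased, biallelic records: every GT field must be
#' `|`-separated with no missing allele; multi-allelic sites and `/`-phased
#' genotypes are rejected with the offending record named. Marker order is
#' taken from the `.map` file when given; VCF bp positions are ignored in
#' favour of the map.
#'
#' @param path path to a (plain-text) VCF with phased GT.
#' @param map optional [genetic_map()] used for marker ordering.
#' @return a [phased_genotypes()].
#' @export
read_phased_vcf <- function(path, map = NULL) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"])))
    stop("multi-allelic site rejected: ",
         fix[grepl(",", fix[, "ALT"]), "ID"][1])
  gt <- vcfR::extract.gt(v, element = "GT")
  ok <- matrix(grepl("^[01]\\|[01]$", gt), nrow(gt), ncol(gt))
  bad <- which(!ok, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("unphased or missing genotype rejected at marker ",
         rownames(gt)[bad[1, 1]], ", individual ", colnames(gt)[bad[1, 2]],
         ' (GT must be "a|b" with a,b in 0/1)')
  ## VCF codes 0 = REF; internal coding is 1 = reference
  a1 <- 1L - matrix(as.integer(substr(gt, 1, 1)), nrow(gt), ncol(gt))
  a2 <- 1L - matrix(as.integer(substr(gt, 3, 3)), nrow(gt), ncol(gt))
  h1 <- t(a1); h2 <- t(a2)
  colnames(h1) <- colnames(h2) <- rownames(gt)
  rownames(h1) <- rownames(h2) <- colnames(gt)
  pg <- phased_genotypes(h1, h2)
  if (!is.null(map)) {
    if (!setequal(map$marker, colnames(pg$h1)))
      stop("VCF/map marker mismatch")
    pg$h1 <- pg$h1[, map$marker, drop = FALSE]
    pg$h2 <- pg$h2[, map$marker, drop = FALSE]
  }
  pg
}

#' Write or read a square matrix table
#'
#' Square tab-separated layout with entity ids as both header row and first
#' column; `read_matrix` returns the matrix with dimnames.
#'
#' @param x square matrix with dimnames.
#' @param path file path.
#' @param seed optional seed recorded in the header comment.
#' @export
write_matrix <- function(x, path, seed = NULL) {
  writeLines(header_comment(seed), path)
  tab <- data.frame(id = rownames(x), unclass(x), check.names = FALSE)
  colnames(tab)[-1] <- colnames(x)
  suppressWarnings(write.table(tab, path, append = TRUE, sep = "\t",
                               quote = FALSE, row.names = FALSE))
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[-1])
  rownames(m) <- tab[[1]]
  m
}

#' Long-format similarity table
#' @param S a similarity matrix with dimnames.
#' @return data.frame `(entity_i, entity_j, value)` over the upper triangle
#'   including the diagonal.
#' @export
similarity_long <- function(S) {
  idx <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
  data.frame(entity_i = rownames(S)[idx[, 1]],
             entity_j = colnames(S)[idx[, 2]],
             value = S[idx], stringsAsFactors = FALSE)
}

#' Generate the worked-example fixture files
#'
#' Writes the two-parent, three-marker dataset used throughout the
#' documentation: ordered haplotypes 1-1-1/2-2-2 and 1-2-1/2-1-2, a map built
#' from adjacent recombination fractions (0.1, 0.2) via [haldane()], marker
#' effects (1, 0.2, 0.02), and a README listing the expected outputs (gamete
#' MSVs 0.3461 and 0.1837, similarity 0.2449, standardised similarity
#' ~0.9713).
#'
#' @param dir writable target directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
make_fixtures <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ex <- worked_example()
  paths <- c(haplotypes = file.path(dir, "parents_haplotypes.tsv"),
             map = file.path(dir, "parents.map"),
             effects = file.path(dir, "parents_effects.tsv"),
             readme = file.path(dir, "README.txt"))
  write_haplotypes(ex$pg, paths["haplotypes"])
  write_map(ex$map, paths["map"])
  write_effects(ex$effects, paths["effects"])
  writeLines(c(
    "Worked-example fixture: two parents, one chromosome, three markers.",
    "Haplotypes 1-1-1/2-2-2 (parent1) and 1-2-1/2-1-2 (parent2);",
    "adjacent recombination fractions 0.1 and 0.2 (Haldane map);",
    "additive marker effects 1, 0.2, 0.02.",
    "",
    "Expected outputs:",
    "  gamete MSV parent1            0.3461",
    "  gamete MSV parent2            0.1837",
    "  pairwise similarity           0.2449",
    "  standardised similarity k_12  0.2449/sqrt(0.3461*0.1837) = 0.9713",
    "  zygote MSV of the pair        0.3461 + 0.1837 = 0.5298"),
    paths["readme"])
  invisible(paths)
}

#' In-memory worked example
#'
#' The same two-parent, three-marker dataset as [make_fixtures()], as ready
#' objects.
#'
#' @return list with `pg`, `map`, `effects`, `theta`.
#' @export
worked_example <- function() {
  h1 <- rbind(parent1 = c(1L, 1L, 1L), parent2 = c(1L, 0L, 1L))
  h2 <- rbind(parent1 = c(0L, 0L, 0L), parent2 = c(0L, 1L, 0L))
  colnames(h1) <- colnames(h2) <- paste0("m", 1:3)
  pg <- phased_genotypes(h1, h2, sex = c("M", "F"))
  theta <- c(0.1, 0.2)
  map <- map_from_theta(theta, chrom = "1", markers = colnames(h1))
  effects <- marker_effects(c(1, 0.2, 0.02), traits = "trait",
                            markers = colnames(h1))
  list(pg = pg, map = map, effects = effects, theta = theta)
}
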