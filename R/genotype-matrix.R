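#' Construct a diploid biallelic genotype matrix
#'
#' The central container of the package: diploid calls for a set of
#' individuals at a set of biallelic loci, together with the mapping of
#' individuals to populations. Genotypes are stored as the count of the
#' alternate allele (0 = ref/ref, 1 = heterozygote, 2 = alt/alt, `NA` =
#' missing). The unordered pairs "0/1" and "1/0" are the same genotype and
#' both map to 1; no nucleotide semantics are retained because every
#' downstream statistic is invariant to allele relabelling.
#'
#' @param geno integer (or coercible) matrix, individuals in rows and loci in
#'   columns, values in `{0, 1, 2, NA}`. Row and column names are required
#'   and must be unique; they become the individual and locus ids.
#' @param pop_of named character vector mapping every individual id to its
#'   population id.
#' @return An object of class `geno_matrix`: a list with elements `geno`
#'   (the integer matrix) and `pops` (population id per individual, in row
#'   order).
#' @export
genotype_matrix <- function(geno, pop_of) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("genotype matrix needs individual (row) and locus (column) names")
  if (anyDuplicated(rownames(geno)))
    stop("duplicate individual ids: ",
         paste(unique(rownames(geno)[duplicated(rownames(geno))]), collapse = ", "))
  if (anyDuplicated(colnames(geno)))
    stop("duplicate locus ids")
  bad <- !is.na(geno) & !(geno %in% 0:2)
  if (any(bad))
    stop("genotype calls must be 0, 1, 2 or NA (alt-allele dosage)")
  missing_pop <- setdiff(rownames(geno), names(pop_of))
  if (length(missing_pop))
    stop("individuals absent from population mapping: ",
         paste(missing_pop, collapse = ", "))
  pops <- as.character(pop_of[rownames(geno)])
  names(pops) <- rownames(geno)
  structure(list(geno = geno, pops = pops), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d individuals x %d loci, %d populations, %.1f%% missing\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$pops)),
              100 * mean(is.na(x$geno))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @param g a `geno_matrix`.
#' @export
individual_ids <- function(g) rownames(g$geno)

#' @rdname genotype_matrix
#' @export
locus_ids <- function(g) colnames(g$geno)

#' @rdname genotype_matrix
#' @export
population_ids <- function(g) unique(unname(g$pops))

#' Subset a genotype matrix by individuals and/or loci
#'
#' @param g a `geno_matrix`.
#' @param individuals,loci character vectors of ids to keep (default: all).
#' @return a `geno_matrix`.
#' @export
subset_genotypes <- function(g, individuals = individual_ids(g),
                             loci = locus_ids(g)) {
  if (!length(individuals)) stop("subset would retain zero individuals")
  if (!length(loci)) stop("subset would retain zero loci")
  genotype_matrix(g$geno[individuals, loci, drop = FALSE], g$pops)
}

#' Per-individual and per-locus missingness
#'
#' @param g a `geno_matrix`.
#' @return named numeric vector of missing-call fractions.
#' @export
sample_missingness <- function(g) rowMeans(is.na(g$geno))

#' @rdname sample_missingness
#' @export
locus_missingness <- function(g) colMeans(is.na(g$geno))
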