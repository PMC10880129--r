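#' Per-population allele frequencies and gene-copy counts
#'
#' Frequencies are computed over called gene copies only. For every
#' (population, locus) cell the table records the number of called gene
#' copies (2 x called genotypes), the count of alternate-allele copies, and
#' the count of heterozygous genotypes; cells with zero called copies are
#' flagged undefined (`NA`).
#'
#' @param g a [genotype_matrix()].
#' @return an object of class `allele_freq_table`: list with matrices
#'   (populations x loci) `n` (gene copies), `alt` (alt copies), `het`
#'   (het genotypes), `n_ind` (called genotypes) and `p_alt` (alt-allele
#'   frequency, `NA` where undefined).
#' @export
allele_frequencies <- function(g) {
  pops <- population_ids(g)
  loci <- locus_ids(g)
  agg <- function(f) {
    m <- t(vapply(pops, function(p) {
      f(g$geno[g$pops == p, , drop = FALSE])
    }, numeric(length(loci))))
    dimnames(m) <- list(pops, loci)
    m
  }
  n_ind <- agg(function(m) colSums(!is.na(m)))
  alt <- agg(function(m) colSums(m, na.rm = TRUE))
  het <- agg(function(m) colSums(m == 1L, na.rm = TRUE))
  n <- 2 * n_ind
  structure(list(pops = pops, loci = loci, n = n, alt = alt, het = het,
                 n_ind = n_ind,
                 p_alt = ifelse(n > 0, alt / n, NA_real_)),
            class = "allele_freq_table")
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d populations x %d loci\n",
              length(x$pops), length(x$loci)))
  invisible(x)
}

#' Observed heterozygosity per population and locus
#'
#' H_O = heterozygous calls / called genotypes. The per-population value is
#' the mean over loci with at least one called genotype.
#'
#' @param g a [genotype_matrix()] or an `allele_freq_table`.
#' @return list with `per_locus` (populations x loci matrix) and
#'   `per_population` (named vector of means over defined loci).
#' @export
observed_heterozygosity <- function(g) {
  f <- if (inherits(g, "allele_freq_table")) g else allele_frequencies(g)
  ho <- ifelse(f$n_ind > 0, f$het / f$n_ind, NA_real_)
  list(per_locus = ho, per_population = rowMeans(ho, na.rm = TRUE))
}

#' Expected heterozygosity (gene diversity) per population and locus
#'
#' Plain mode is `1 - sum(p^2)`; unbiased mode (the default, matching the
#' hierfstat/`basic.stats` family) multiplies by `2n/(2n - 1)`, i.e. the
#' probability that two gene copies drawn without replacement differ.
#'
#' @param f an `allele_freq_table`.
#' @param unbiased logical; use the small-sample correction (default TRUE).
#' @return list with `per_locus` matrix and `per_population` means.
#' @export
expected_heterozygosity <- function(f, unbiased = TRUE) {
  p <- f$p_alt
  he <- 2 * p * (1 - p)
  if (unbiased) {
    he <- ifelse(f$n >= 2, he * f$n / (f$n - 1), NA_real_)
  }
  list(per_locus = he, per_population = rowMeans(he, na.rm = TRUE))
}

# expected distinct alleles in a subsample of g copies, one locus:
# counts = copies per allele, N = sum(counts)
rarefied_allele_count <- function(counts, g) {
  N <- sum(counts)
  sum(1 - choose(N - counts, g) / choose(N, g))
}

#' Rarefied allelic richness per population and locus
#'
#' A_R is the expected number of distinct alleles in a random subsample of
#' `g_copies` gene copies (hypergeometric rarefaction). Loci where a
#' population has fewer than `g_copies` called copies are skipped for that
#' population (flagged `NA`) so values stay comparable across populations.
#' The default of 5 gene copies standardises to the smallest samples in a
#' 3-7 individuals per population design with missing data.
#'
#' @param f an `allele_freq_table`.
#' @param g_copies rarefaction size in gene copies (>= 1).
#' @return list with `per_locus` matrix, `per_population` means, and
#'   `n_skipped` (loci per population with insufficient copies).
#' @export
allelic_richness <- function(f, g_copies = 5) {
  stopifnot(g_copies >= 1)
  ar <- matrix(NA_real_, nrow(f$n), ncol(f$n), dimnames = dimnames(f$n))
  ok <- !is.na(f$p_alt) & f$n >= g_copies
  idx <- which(ok)
  ar[idx] <- vapply(idx, function(i) {
    rarefied_allele_count(c(f$alt[i], f$n[i] - f$alt[i]), g_copies)
  }, numeric(1))
  list(per_locus = ar,
       per_population = rowMeans(ar, na.rm = TRUE),
       n_skipped = rowSums(!ok))
}

#' Inbreeding coefficient
#'
#' Per locus, `F_IS = 1 - H_O / H_E` where `H_E > 0`. The per-population
#' multilocus value is the ratio-of-sums aggregate
#' `1 - sum(H_O) / sum(H_E)` over loci where both are defined, which avoids
#' the instability of averaging per-locus ratios at near-monomorphic loci.
#'
#' @param ho,he outputs of [observed_heterozygosity()] and
#'   [expected_heterozygosity()] (the `per_locus` matrices are used).
#' @return list with `per_locus` matrix and `per_population` multilocus
#'   values (`NA` where every locus has `H_E` undefined or zero).
#' @export
inbreeding_coefficient <- function(ho, he) {
  hol <- ho$per_locus
  hel <- he$per_locus
  stopifnot(identical(dim(hol), dim(hel)))
  fis <- ifelse(!is.na(hel) & hel > 0, 1 - hol / hel, NA_real_)
  both <- !is.na(hol) & !is.na(hel)
  num <- rowSums(ifelse(both, hol, 0))
  den <- rowSums(ifelse(both, hel, 0))
  per_pop <- ifelse(den > 0, 1 - num / den, NA_real_)
  names(per_pop) <- rownames(hol)
  list(per_locus = fis, per_population = per_pop)
}

#' Per-population diversity summary table
#'
#' Assembles N_A (mean observed alleles per locus), rarefied allelic
#' richness, observed and expected heterozygosity and the multilocus
#' inbreeding coefficient into one row per population.
#'
#' @param g a [genotype_matrix()].
#' @param g_copies rarefaction size for A_R, in gene copies.
#' @param unbiased_he use the unbiased expected-heterozygosity estimator.
#' @return data frame with columns `pop_id`, `n_ind`, `N_A`, `A_R`, `H_O`,
#'   `H_E`, `F_IS`; per-locus matrices attached as attribute `per_locus`
#'   for auditing.
#' @export
diversity_table <- function(g, g_copies = 5, unbiased_he = TRUE) {
  f <- allele_frequencies(g)
  ho <- observed_heterozygosity(f)
  he <- expected_heterozygosity(f, unbiased = unbiased_he)
  ar <- allelic_richness(f, g_copies = g_copies)
  fis <- inbreeding_coefficient(ho, he)
  # observed allele count per pop x locus: 2 if polymorphic or any het, else 1
  n_alleles <- ifelse(is.na(f$p_alt), NA_real_,
                      ifelse(f$p_alt > 0 & f$p_alt < 1, 2, 1))
  out <- data.frame(
    pop_id = f$pops,
    n_ind = as.vector(table(factor(g$pops, levels = f$pops))),
    N_A = rowMeans(n_alleles, na.rm = TRUE),
    A_R = ar$per_population[f$pops],
    H_O = ho$per_population[f$pops],
    H_E = he$per_population[f$pops],
    F_IS = fis$per_population[f$pops],
    row.names = NULL)
  attr(out, "per_locus") <- list(H_O = ho$per_locus, H_E = he$per_locus,
                                 A_R = ar$per_locus, F_IS = fis$per_locus)
  out
}
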