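#' Exact Hardy-Weinberg distribution for a biallelic locus
#'
#' Probability of each possible heterozygote count conditional on the
#' observed allele counts, under random union of gametes. Computed in log
#' space over the support (heterozygote counts with the parity of the minor
#' allele count) and normalised, so it is stable for large samples.
#'
#' @param n_het observed heterozygote count.
#' @param n_ind called diploid genotypes.
#' @param n_minor copies of the rarer allele (any allele works; the
#'   distribution is symmetric in the allele labels).
#' @return list with `support` (possible het counts), `prob` (their
#'   probabilities, summing to 1) and `p_obs` (probability of the observed
#'   count).
#' @keywords internal
hwe_het_distribution <- function(n_het, n_ind, n_minor) {
  n_major <- 2 * n_ind - n_minor
  hmax <- min(n_minor, n_major)
  support <- seq(n_minor %% 2, hmax, by = 2)
  n_aa <- (n_minor - support) / 2      # minor homozygotes
  n_AA <- n_ind - support - n_aa       # major homozygotes
  logw <- lfactorial(n_ind) - lfactorial(n_AA) - lfactorial(support) -
    lfactorial(n_aa) + support * log(2)
  w <- exp(logw - max(logw))
  prob <- w / sum(w)
  list(support = support, prob = prob,
       p_obs = prob[match(n_het, support)])
}

#' Exact Hardy-Weinberg test per population and locus
#'
#' For every (population, locus) cell with at least `min_genotypes` called
#' genotypes, computes the exact conditional test of Hardy-Weinberg
#' proportions: the one-sided heterozygote-deficit p-value (probability of
#' the observed or a smaller heterozygote count) and the two-sided p-value
#' (sum of outcomes no more probable than the observed one). Monomorphic
#' cells get p = 1 by convention and are flagged. The per-population
#' deviating-locus fraction at `alpha` uses the two-sided p.
#'
#' @param g a [genotype_matrix()] or `allele_freq_table`.
#' @param alpha significance level for the deviating-locus fraction.
#' @param min_genotypes minimum called genotypes per cell (default 2).
#' @return list of class `hwe_result`: matrices `p_two_sided`,
#'   `p_deficit`, `p_excess`, logical `monomorphic`, and a data frame
#'   `per_population` with the fraction of testable loci deviating at
#'   `alpha` and the fraction of deviating loci that are homozygote-excess.
#' @export
hwe_exact_test <- function(g, alpha = 0.05, min_genotypes = 2) {
  f <- if (inherits(g, "allele_freq_table")) g else allele_frequencies(g)
  dims <- dim(f$n)
  dn <- dimnames(f$n)
  p2 <- pdef <- pexc <- matrix(NA_real_, dims[1], dims[2], dimnames = dn)
  mono <- matrix(FALSE, dims[1], dims[2], dimnames = dn)
  testable <- f$n_ind >= min_genotypes
  for (i in which(testable)) {
    n_ind <- f$n_ind[i]
    alt <- f$alt[i]
    n_minor <- min(alt, 2 * n_ind - alt)
    if (n_minor == 0) {
      p2[i] <- pdef[i] <- pexc[i] <- 1
      mono[i] <- TRUE
      next
    }
    d <- hwe_het_distribution(f$het[i], n_ind, n_minor)
    obs <- match(f$het[i], d$support)
    pdef[i] <- sum(d$prob[seq_len(obs)])
    pexc[i] <- sum(d$prob[obs:length(d$prob)])
    p2[i] <- sum(d$prob[d$prob <= d$p_obs * (1 + 1e-7)])
  }
  dev <- !is.na(p2) & p2 < alpha & !mono
  n_testable <- rowSums(!is.na(p2) & !mono)
  excess_homo <- dev & pdef < pexc
  per_population <- data.frame(
    pop_id = rownames(p2),
    n_testable = n_testable,
    n_deviating = rowSums(dev),
    frac_deviating = ifelse(n_testable > 0, rowSums(dev) / n_testable, NA_real_),
    frac_deficit_het = ifelse(rowSums(dev) > 0,
                              rowSums(excess_homo) / rowSums(dev), NA_real_),
    row.names = NULL)
  structure(list(p_two_sided = p2, p_deficit = pdef, p_excess = pexc,
                 monomorphic = mono, alpha = alpha,
                 per_population = per_population),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("Exact Hardy-Weinberg test (alpha =", x$alpha, ")\n")
  print(x$per_population)
  invisible(x)
}

#' Fraction of loci deviating from Hardy-Weinberg in any population
#'
#' A locus counts as deviating when its two-sided exact p-value falls below
#' `alpha` in at least one population where it is testable.
#'
#' @param hwe an `hwe_result`.
#' @param alpha significance level (defaults to the one used in the test).
#' @return a single proportion.
#' @export
hwe_locus_deviation_fraction <- function(hwe, alpha = hwe$alpha) {
  p2 <- hwe$p_two_sided
  testable <- colSums(!is.na(p2) & !hwe$monomorphic) > 0
  dev <- colSums(!is.na(p2) & p2 < alpha & !hwe$monomorphic) > 0
  sum(dev & testable) / sum(testable)
}
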