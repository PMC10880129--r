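# --- independent oracles ----------------------------------------------------

# gene diversity by exhaustive enumeration of unordered pairs of gene copies
pair_enum_he <- function(counts) {
  copies <- rep(seq_along(counts), counts)
  pairs <- combn(length(copies), 2)
  mean(copies[pairs[1, ]] != copies[pairs[2, ]])
}

# rarefied allele count by exhaustive enumeration of all size-g subsamples
subsample_enum_ar <- function(counts, g) {
  copies <- rep(seq_along(counts), counts)
  subs <- combn(length(copies), g)
  mean(apply(subs, 2, function(ix) length(unique(copies[ix]))))
}

# Levene's closed-form exact HWE probability of a heterozygote count
levene_prob <- function(n_het, n_ind, n_alt) {
  n_aa <- (n_alt - n_het) / 2
  n_AA <- n_ind - n_het - n_aa
  factorial(n_ind) / (factorial(n_AA) * factorial(n_het) * factorial(n_aa)) *
    2^n_het * factorial(n_alt) * factorial(2 * n_ind - n_alt) /
    factorial(2 * n_ind)
}

# --- allele frequencies -----------------------------------------------------

test_that("allele frequencies are computed over called copies only", {
  m <- matrix(c(0L, 1L, 2L,        # p_alt = 0.5 over 6 copies
                NA, NA, NA,        # undefined
                0L, 0L, 0L), 3, 3) # monomorphic
  g <- toy_genotypes(m, rep("p1", 3))
  f <- allele_frequencies(g)
  expect_equal(unname(f$p_alt[1, 1]), 0.5)
  expect_equal(unname(f$n[1, 1]), 6)
  expect_true(is.na(f$p_alt[1, 2]))
  expect_equal(unname(f$p_alt[1, 3]), 0)
})

test_that("observed heterozygosity is het calls over called genotypes", {
  m <- cbind(c(1L, 1L, 0L, 2L, 0L),   # 2 of 5 heterozygous
             rep(0L, 5),              # all homozygous
             rep(1L, 5))              # all heterozygous
  g <- toy_genotypes(m, rep("p1", 5))
  ho <- observed_heterozygosity(g)
  expect_equal(unname(ho$per_locus[1, ]), c(0.4, 0, 1))
})

# --- expected heterozygosity ------------------------------------------------

test_that("expected heterozygosity matches plain and unbiased definitions", {
  f <- freq_table(alt = matrix(c(5, 10, 0), 1), n = matrix(c(10, 20, 10), 1))
  plain <- expected_heterozygosity(f, unbiased = FALSE)
  expect_equal(unname(plain$per_locus[1, ]), c(0.5, 0.5, 0))
  unb <- expected_heterozygosity(f, unbiased = TRUE)
  expect_equal(unname(unb$per_locus[1, 1]), 2 * 5 * 5 / (10 * 9))
  expect_equal(unname(unb$per_locus[1, 3]), 0)
})

test_that("unbiased H_E equals pair-enumeration probability for all N <= 12", {
  for (N in c(2, 5, 8, 12)) for (alt in 0:N) {
    f <- freq_table(alt = matrix(alt, 1), n = matrix(N, 1))
    he <- expected_heterozygosity(f, unbiased = TRUE)$per_locus[1, 1]
    expect_equal(unname(he), pair_enum_he(c(alt, N - alt)),
                 tolerance = 1e-12)
  }
})

# --- allelic richness -------------------------------------------------------

test_that("allelic richness has its closed-form and boundary values", {
  f <- freq_table(alt = matrix(c(5, 0, 3), 1), n = matrix(c(10, 10, 10), 1))
  ar <- allelic_richness(f, g_copies = 2)
  expect_equal(unname(ar$per_locus[1, 1]), 70 / 45, tolerance = 1e-12)
  expect_equal(unname(ar$per_locus[1, 2]), 1)       # monomorphic
  full <- allelic_richness(f, g_copies = 10)        # g = N: observed count
  expect_equal(unname(full$per_locus[1, ]), c(2, 1, 2))
})

test_that("loci with fewer copies than the rarefaction size are skipped", {
  f <- freq_table(alt = matrix(c(2, 1), 1), n = matrix(c(4, 10), 1))
  ar <- allelic_richness(f, g_copies = 5)
  expect_true(is.na(ar$per_locus[1, 1]))
  expect_false(is.na(ar$per_locus[1, 2]))
  expect_equal(unname(ar$n_skipped[1]), 1)
  expect_error(allelic_richness(f, g_copies = 0))
})

# --- inbreeding coefficient -------------------------------------------------

test_that("F_IS spans random mating to complete homozygote excess", {
  ho <- list(per_locus = matrix(c(0.3, 0, 0.2), 1,
                                dimnames = list("p1", c("a", "b", "c"))))
  he <- list(per_locus = matrix(c(0.3, 0.5, 0.4), 1,
                                dimnames = list("p1", c("a", "b", "c"))))
  fis <- inbreeding_coefficient(ho, he)
  expect_equal(unname(fis$per_locus[1, ]), c(0, 1, 0.5))
  # multilocus value is ratio-of-sums, not mean of ratios
  expect_equal(unname(fis$per_population), 1 - 0.5 / 1.2)
})

# --- exact Hardy-Weinberg test ----------------------------------------------

test_that("exact HWE probabilities match Levene's closed form (n <= 8)", {
  for (n_ind in 2:8) for (n_alt in 1:n_ind) {
    hmax <- min(n_alt, 2 * n_ind - n_alt)
    support <- seq(n_alt %% 2, hmax, by = 2)
    d <- urbanpopgen:::hwe_het_distribution(support[1], n_ind, n_alt)
    expect_equal(d$support, support)
    oracle <- vapply(support, levene_prob, numeric(1), n_ind = n_ind,
                     n_alt = n_alt)
    expect_equal(d$prob, oracle, tolerance = 1e-12)
    expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  }
})

test_that("exact HWE test reports the documented boundary cases", {
  # perfect HWE proportions: observed count is the conditional mode
  m <- c(rep(0L, 25), rep(1L, 50), rep(2L, 25))
  g <- toy_genotypes(matrix(m, 100, 1), rep("p1", 100))
  res <- hwe_exact_test(g)
  expect_gt(res$p_two_sided[1, 1], 0.9)

  # (AA=2, Aa=0, aa=2): one-sided deficit p = 6/70
  g <- toy_genotypes(matrix(c(0L, 0L, 2L, 2L), 4, 1), rep("p1", 4))
  res <- hwe_exact_test(g)
  expect_equal(unname(res$p_deficit[1, 1]), 6 / 70, tolerance = 1e-12)

  # all heterozygous: deficit p = 1
  g <- toy_genotypes(matrix(rep(1L, 4), 4, 1), rep("p1", 4))
  res <- hwe_exact_test(g)
  expect_equal(unname(res$p_deficit[1, 1]), 1)

  # monomorphic: p = 1 by convention, flagged
  g <- toy_genotypes(matrix(rep(0L, 4), 4, 1), rep("p1", 4))
  res <- hwe_exact_test(g)
  expect_true(res$monomorphic[1, 1])
  expect_equal(unname(res$p_two_sided[1, 1]), 1)
})

test_that("per-population deviating fraction counts two-sided rejections", {
  # strong homozygote excess at two loci, HWE at none
  m <- cbind(c(rep(0L, 10), rep(2L, 10)), c(rep(0L, 10), rep(2L, 10)))
  g <- toy_genotypes(m, rep("p1", 20))
  res <- hwe_exact_test(g)
  expect_equal(res$per_population$frac_deviating, 1)
  expect_equal(res$per_population$frac_deficit_het, 1)
  expect_equal(hwe_locus_deviation_fraction(res), 1)
})
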