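two_pop_table <- function(pa, pb, n = 10) {
  freq_table(alt = rbind(round(pa * n), round(pb * n)),
             n = matrix(n, 2, length(pa)))
}

test_that("Nei distance matches hand-derived values and boundary cases", {
  f <- two_pop_table(0.8, 0.3, n = 10)
  expect_equal(nei_distance(f, "p1", "p2"), 0.502386, tolerance = 1e-4)
  # identical frequency vectors: D = 0
  f <- two_pop_table(c(0.2, 0.7), c(0.2, 0.7))
  expect_equal(nei_distance(f, "p1", "p2"), 0, tolerance = 1e-12)
  # fixed for alternate alleles: I = 0 -> infinite sentinel
  f <- two_pop_table(0, 1)
  expect_identical(nei_distance(f, "p1", "p2"), Inf)
})

test_that("pairwise F_ST matches the hand-derived Nei estimator", {
  f <- two_pop_table(0.8, 0.3, n = 10)
  expect_equal(fst_pairwise(f, "p1", "p2"), 0.252525, tolerance = 1e-4)
  f <- two_pop_table(0, 1)
  expect_equal(fst_pairwise(f, "p1", "p2"), 1)
  f <- two_pop_table(1, 1)
  expect_warning(v <- fst_pairwise(f, "p1", "p2"), "undefined")
  expect_equal(v, 0)
})

test_that("distances are symmetric in arguments and invariant to relabelling", {
  withr::with_seed(8, {
    pa <- runif(20); pb <- runif(20)
  })
  f <- two_pop_table(pa, pb, n = 20)
  expect_equal(nei_distance(f, "p1", "p2"), nei_distance(f, "p2", "p1"))
  expect_equal(fst_pairwise(f, "p1", "p2"), fst_pairwise(f, "p2", "p1"))
  # allele relabelling (alt <-> ref) and locus order leave Nei D unchanged
  f_flip <- two_pop_table(1 - pa, 1 - pb, n = 20)
  expect_equal(nei_distance(f_flip, "p1", "p2"), nei_distance(f, "p1", "p2"),
               tolerance = 1e-12)
  ord <- rev(seq_along(pa))
  f_perm <- two_pop_table(pa[ord], pb[ord], n = 20)
  expect_equal(nei_distance(f_perm, "p1", "p2"), nei_distance(f, "p1", "p2"),
               tolerance = 1e-12)
})

test_that("Weir-Cockerham theta is close to truth on a balanced design", {
  # moderate divergence, large equal samples: both estimators should land
  # near the parametric value and each other
  withr::with_seed(3, {
    p <- rbeta(400, 2, 2)
    fst_true <- 0.15
    a <- p + rnorm(400, 0, sqrt(fst_true * p * (1 - p)))
    b <- p + rnorm(400, 0, sqrt(fst_true * p * (1 - p)))
    a <- pmin(pmax(a, 0), 1); b <- pmin(pmax(b, 0), 1)
  })
  f <- freq_table(alt = rbind(round(a * 200), round(b * 200)),
                  n = matrix(200, 2, 400),
                  het = rbind(round(2 * a * (1 - a) * 100),
                              round(2 * b * (1 - b) * 100)))
  wc <- fst_pairwise(f, "p1", "p2", method = "wc")
  nei <- fst_pairwise(f, "p1", "p2", method = "nei")
  expect_gt(wc, 0.05); expect_lt(wc, 0.35)
  expect_equal(wc, nei, tolerance = 0.25)
})

test_that("distance_matrix is symmetric with zero diagonal and propagates Inf", {
  withr::with_seed(4, {
    alt <- matrix(sample(0:10, 4 * 30, replace = TRUE), 4)
  })
  f <- freq_table(alt = alt, n = matrix(10, 4, 30))
  d <- distance_matrix(f, "nei")
  expect_identical(unclass(d)[, ], t(unclass(d)[, ]))
  expect_true(all(diag(d) == 0))
  d2 <- distance_matrix(f, "fst")
  expect_true(all(d2[upper.tri(d2)] <= 1 + 1e-12))

  # identical populations give an all-zero matrix
  f_id <- freq_table(alt = rbind(c(3, 7), c(3, 7)), n = matrix(10, 2, 2))
  expect_true(all(distance_matrix(f_id, "nei") == 0))

  f_inf <- freq_table(alt = rbind(0, 10), n = matrix(10, 2, 1))
  expect_warning(d3 <- distance_matrix(f_inf, "nei"), "infinite")
  expect_identical(unname(d3["p1", "p2"]), Inf)
})

test_that("F_ST under pure drift increases with generations of isolation", {
  mean_fst <- vapply(c(5, 10, 20, 40, 80), function(T) {
    reps <- vapply(1:6, function(s) {
      scn <- sim_scenario(n_pops = 2, habitat_of = c("RA", "RA"),
                          n_loci = 100, N = 50, selfing = 0,
                          generations = T, missing_rate = 0,
                          samples_per_pop = c(25, 25),
                          migration = list(model = "none"),
                          seed = 1000 * T + s)
      sim <- simulate_scenario(scn)
      f <- allele_frequencies(sim$genotypes)
      fst_pairwise(f, "pop01", "pop02")
    }, numeric(1))
    mean(reps)
  }, numeric(1))
  expect_equal(cor(mean_fst, seq_along(mean_fst), method = "spearman"), 1)
})

test_that("PCoA recovers planar configurations and closed-form eigenvalues", {
  # two points at distance d: single positive eigenvalue d^2/2
  d <- dist_matrix_obj(matrix(c(0, 3, 3, 0), 2,
                              dimnames = list(c("a", "b"), c("a", "b"))))
  res <- pcoa_ordination(d)
  pos <- res$eigenvalues[res$eigenvalues > 1e-9]
  expect_equal(pos, 4.5, tolerance = 1e-9)

  # identical points: no positive eigenvalues above numerical zero
  d0 <- dist_matrix_obj(matrix(0, 3, 3, dimnames = list(letters[1:3],
                                                        letters[1:3])))
  expect_true(all(abs(pcoa_ordination(d0)$eigenvalues) < 1e-12))
})

test_that("PCoA eigenvalue sum equals the trace of the centered matrix", {
  d <- dist_matrix_obj(random_dist(7, seed = 6))
  res <- pcoa_ordination(d)
  n <- nrow(d)
  C <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * C %*% (unclass(d)^2) %*% C
  expect_equal(sum(res$eigenvalues), sum(diag(B)), tolerance = 1e-9)
  # coordinates agree with cmdscale up to sign
  cm <- cmdscale(as.dist(d), k = ncol(res$coordinates))
  for (k in seq_len(ncol(cm)))
    expect_equal(abs(res$coordinates[, k]), abs(cm[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)
})
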