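# all permutations of a vector, for exhaustive oracles on tiny inputs
perm_all <- function(v) {
  if (length(v) <= 1) return(list(v))
  do.call(c, lapply(seq_along(v), function(i)
    lapply(perm_all(v[-i]), function(p) c(v[i], p))))
}

test_that("Mantel test: identity, negation and degenerate inputs", {
  x <- dist_matrix_obj(random_dist(10, seed = 1))
  m <- mantel_test(x, x, n_perm = 199, seed = 3)
  expect_equal(m$observed, 1)
  expect_equal(m$p, 1 / 200)

  neg <- max(x) + 1 - unclass(x); diag(neg) <- 0
  expect_equal(mantel_test(x, dist_matrix_obj(neg), n_perm = 99,
                           seed = 1)$observed, -1)

  const <- dist_matrix_obj(matrix(1, 5, 5) - diag(5),
                           kind = "constant")
  dimnames(const) <- dimnames(random_dist(5))
  expect_error(mantel_test(dist_matrix_obj(random_dist(5)), const,
                           n_perm = 99, seed = 1), "constant")
})

test_that("Mantel p equals the exhaustive 24-relabelling oracle on 4x4", {
  x4 <- dist_matrix_obj(random_dist(4, seed = 2))
  y4 <- dist_matrix_obj(random_dist(4, seed = 9))
  m4 <- suppressMessages(mantel_test(x4, y4, n_perm = 9999, seed = 5))
  obs <- cor(x4[upper.tri(x4)], y4[upper.tri(y4)])
  rs <- vapply(perm_all(1:4), function(p) {
    yp <- unclass(y4)[p, p]
    cor(x4[upper.tri(x4)], yp[upper.tri(yp)])
  }, numeric(1))
  expect_equal(m4$p, mean(rs >= obs - 1e-12), tolerance = 1e-12)
})

test_that("partial Mantel handles identity, degeneracy and weak covariates", {
  x <- dist_matrix_obj(random_dist(9, seed = 4))
  z <- dist_matrix_obj(random_dist(9, seed = 5))
  pm <- partial_mantel_test(x, x, z, n_perm = 99, seed = 2)
  expect_equal(pm$observed, 1, tolerance = 1e-12)
  expect_error(partial_mantel_test(x, z, z, n_perm = 99, seed = 2),
               "perfectly correlated")
  # covariate uncorrelated with both: partial r tracks the plain Mantel r
  y <- dist_matrix_obj(random_dist(9, seed = 6))
  plain <- mantel_test(x, y, n_perm = 99, seed = 3)$observed
  part <- partial_mantel_test(x, y, z, n_perm = 99, seed = 3)$observed
  expect_equal(part, plain, tolerance = 0.15)
})

test_that("permutation results are seed-reproducible and label-order invariant", {
  x <- dist_matrix_obj(random_dist(8, seed = 7))
  y <- dist_matrix_obj(random_dist(8, seed = 8))
  a <- mantel_test(x, y, n_perm = 199, seed = 11)
  b <- mantel_test(x, y, n_perm = 199, seed = 11)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$p, b$p)
  ord <- rev(rownames(y))
  c_ <- mantel_test(x, dist_matrix_obj(unclass(y)[ord, ord]),
                    n_perm = 199, seed = 11)
  expect_equal(c_$observed, a$observed, tolerance = 1e-12)
  expect_identical(c_$p, a$p)
})

test_that("cross-group observed r equals an independent flat computation", {
  x <- dist_matrix_obj(random_dist(11, seed = 1))
  y <- dist_matrix_obj(random_dist(11, seed = 2))
  groups <- setNames(rep(c("RA", "UA"), c(5, 6)), rownames(x))
  cg <- cross_group_correlation_ci(x, y, groups, "RA", "UA",
                                   n_perm = 50, seed = 3)
  # flat oracle: explicit loop over the 5 x 6 between-group pairs
  xs <- ys <- c()
  for (a in names(groups)[groups == "RA"]) for (b in names(groups)[groups == "UA"]) {
    xs <- c(xs, x[a, b]); ys <- c(ys, y[a, b])
  }
  expect_equal(cg$observed, cor(xs, ys), tolerance = 1e-12)
  expect_equal(cg$n_pairs, 30)
})

test_that("cross-group null on 2+2 groups stays within the enumerable set", {
  x <- dist_matrix_obj(random_dist(4, seed = 12))
  y <- dist_matrix_obj(random_dist(4, seed = 13))
  groups <- setNames(c("RA", "RA", "UA", "UA"), rownames(x))
  cg <- cross_group_correlation_ci(x, y, groups, "RA", "UA",
                                   n_perm = 400, seed = 4)
  # exhaustive null: all assignments of the 4 labels into two groups of 2
  combos <- combn(4, 2)
  enum <- apply(combos, 2, function(ix) {
    g1 <- rownames(x)[ix]; g2 <- setdiff(rownames(x), g1)
    ij <- expand.grid(a = g1, b = g2, stringsAsFactors = FALSE)
    cor(x[cbind(ij$a, ij$b)], y[cbind(ij$a, ij$b)])
  })
  for (r in unique(round(cg$replicates, 10)))
    expect_true(any(abs(enum - r) < 1e-9))
})

test_that("monotone cross-group association is flagged against its null", {
  # y a strictly increasing function of x on every pair
  x <- dist_matrix_obj(random_dist(8, seed = 21))
  y <- dist_matrix_obj(2 * unclass(x) + 0.5 * unclass(x)^2)
  groups <- setNames(rep(c("RA", "UR"), each = 4), rownames(x))
  cg <- cross_group_correlation_ci(x, y, groups, "RA", "UR",
                                   n_perm = 200, seed = 5)
  expect_gt(cg$observed, 0.99)
  expect_error(cross_group_correlation_ci(x, y, groups, "RA", "RA",
                                          n_perm = 10, seed = 1),
               "different")
})

test_that("pair sets respect the combinatorial identities", {
  withr::with_seed(31, {
    habs <- sample(c("RA", "UA", "UP", "UR"), 14, replace = TRUE)
  })
  habs[1:4] <- c("RA", "UA", "UP", "UR")  # every habitat present
  groups <- setNames(habs, sprintf("p%02d", 1:14))
  sets <- build_pair_sets(groups)
  nh <- table(habs)
  for (h in names(nh)[nh >= 2])
    expect_equal(nrow(sets[[h]]$pairs), choose(nh[[h]], 2))
  for (pr in list(c("RA", "UA"), c("UA", "UR"), c("UP", "UR")))
    expect_equal(nrow(sets[[paste(pr, collapse = "_")]]$pairs),
                 nh[[pr[1]]] * nh[[pr[2]]])
  expect_equal(nrow(sets$ALL$pairs), choose(14, 2))
  # no self pairs, no duplicates
  all_p <- sets$ALL$pairs
  expect_true(all(all_p$popA != all_p$popB))
  expect_false(any(duplicated(t(apply(all_p, 1, sort)))))
  expect_error(build_pair_sets(c(p1 = "XX")), "unknown habitat")
})

test_that("habitat-pair resampling means and CIs behave at the boundaries", {
  d <- dist_matrix_obj(random_dist(6, seed = 41))
  groups <- setNames(rep(c("RA", "UA", "UP"), 2), rownames(d))
  sets <- build_pair_sets(groups)

  single <- sets$RA  # one within-RA pair only
  expect_equal(nrow(single$pairs), 1)
  res <- habitat_pair_resample(d, list(single), n_reps = 100, seed = 2)
  v <- d[single$pairs$popA, single$pairs$popB]
  expect_equal(res$summary$mean, v)
  expect_equal(res$summary$ci_low, v)
  expect_equal(res$summary$ci_high, v)

  # {0, 1} equiprobable: mean near 0.5 at 1000 draws
  d2 <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  d2["a", "b"] <- d2["b", "a"] <- 0
  d2["c", "d"] <- d2["d", "c"] <- 1
  ps <- structure(list(label = "two", pairs = data.frame(
    popA = c("a", "c"), popB = c("b", "d"))), class = "pair_set")
  res2 <- habitat_pair_resample(dist_matrix_obj(d2), list(ps),
                                n_reps = 1000, seed = 3)
  expect_gt(res2$summary$mean, 0.45)
  expect_lt(res2$summary$mean, 0.55)
})
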