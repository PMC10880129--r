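#' Container for permutation / resampling results
#'
#' @param observed observed statistic.
#' @param replicates vector of permuted / resampled statistics.
#' @param p permutation p-value, or `NA` for pure resampling CIs.
#' @param seed the seed used.
#' @param ... further named fields stored alongside.
#' @return list of class `resampling_result` with 2.5/97.5 percentile CI.
#' @export
resampling_result <- function(observed, replicates, p = NA_real_,
                              seed = NA_integer_, ...) {
  ci <- stats::quantile(replicates, c(0.025, 0.975), names = FALSE,
                        na.rm = TRUE)
  structure(list(observed = observed, replicates = replicates,
                 ci_low = ci[1], ci_high = ci[2], p = p,
                 n_reps = length(replicates), seed = seed, ...),
            class = "resampling_result")
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("observed = %.4f, 95%% CI of %d replicates = [%.4f, %.4f]%s\n",
              x$observed, x$n_reps, x$ci_low, x$ci_high,
              if (is.na(x$p)) "" else sprintf(", p = %.4g", x$p)))
  invisible(x)
}

# align second matrix to the labels of the first
align_dist <- function(x, y, what = "y") {
  if (is.null(rownames(x)) || is.null(rownames(y)))
    stop("distance matrices must be labelled")
  if (!setequal(rownames(x), rownames(y)))
    stop("distance matrices have different label sets")
  y[rownames(x), rownames(x)]
}

upper_vals <- function(m) m[upper.tri(m)]

#' Mantel permutation test between two distance matrices
#'
#' The observed statistic is the Pearson correlation over off-diagonal
#' entries; the null distribution is built by jointly permuting rows and
#' columns of one matrix (delegated to [vegan::mantel()]). The default
#' p-value is one-sided greater, the vegan convention:
#' `p = (#{r_perm >= r_obs} + 1) / (n_perm + 1)`.
#'
#' @param x,y labelled symmetric matrices with matching label sets; `y` is
#'   re-ordered to `x`'s labels.
#' @param n_perm number of permutations.
#' @param seed integer seed (required; no hidden global state).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return a [resampling_result()] with the permuted correlations as
#'   replicates.
#' @export
mantel_test <- function(x, y, n_perm = 999, seed, alternative = c("greater",
                                                                  "two.sided")) {
  alternative <- match.arg(alternative)
  y <- align_dist(x, y)
  if (any(!is.finite(upper_vals(x))) || any(!is.finite(upper_vals(y))))
    stop("distance matrices must be finite for the Mantel test")
  if (stats::sd(upper_vals(x)) == 0 || stats::sd(upper_vals(y)) == 0)
    stop("constant distance matrix: Mantel r undefined")
  res <- withr::with_seed(seed,
    vegan::mantel(stats::as.dist(x), stats::as.dist(y),
                  permutations = n_perm))
  p <- if (alternative == "greater") res$signif else
    (sum(abs(res$perm) >= abs(res$statistic)) + 1) / (n_perm + 1)
  resampling_result(observed = unname(res$statistic), replicates = res$perm,
                    p = p, seed = seed, alternative = alternative,
                    method = "mantel")
}

#' Partial Mantel test (first-order partial correlation)
#'
#' Correlation between `x` and `y` conditioned on covariate `z`, computed
#' from the three pairwise entry correlations with permutation of `x`
#' (delegated to [vegan::mantel.partial()]).
#'
#' @inheritParams mantel_test
#' @param z covariate distance matrix.
#' @return a [resampling_result()].
#' @export
partial_mantel_test <- function(x, y, z, n_perm = 999, seed,
                                alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  y <- align_dist(x, y)
  z <- align_dist(x, z)
  rxz <- stats::cor(upper_vals(x), upper_vals(z))
  ryz <- stats::cor(upper_vals(y), upper_vals(z))
  if (isTRUE(all.equal(abs(rxz), 1)) || isTRUE(all.equal(abs(ryz), 1)))
    stop("covariate is perfectly correlated with an input matrix; ",
         "partial correlation undefined")
  res <- withr::with_seed(seed,
    vegan::mantel.partial(stats::as.dist(x), stats::as.dist(y),
                          stats::as.dist(z), permutations = n_perm))
  p <- if (alternative == "greater") res$signif else
    (sum(abs(res$perm) >= abs(res$statistic)) + 1) / (n_perm + 1)
  resampling_result(observed = unname(res$statistic), replicates = res$perm,
                    p = p, seed = seed, alternative = alternative,
                    method = "partial_mantel")
}

# between-group (a in g1, b in g2) index pairs for a labelled matrix
between_pairs <- function(labels, pops1, pops2) {
  expand.grid(a = match(pops1, labels), b = match(pops2, labels))
}

#' Correlation between two distance matrices over cross-habitat pairs,
#' with a permutation-null confidence interval
#'
#' The observed statistic is the Pearson correlation of `(x, y)` entries
#' over exactly the between-group pairs (one population from each group).
#' Standard Mantel machinery cannot restrict itself to such pairs, so the
#' null is built directly: population labels are permuted within the union
#' of the two groups (group sizes preserved) and the correlation is
#' recomputed on the induced between-group pairs. The 95% CI of that null
#' is reported, and the observed value is flagged significant when it lies
#' outside. A bootstrap CI of the observed correlation (resampling pairs)
#' is available instead via `method = "bootstrap"`.
#'
#' @param x,y labelled symmetric matrices over (at least) the two groups.
#' @param groups named character vector mapping population id to habitat.
#' @param g1,g2 the two habitat labels (must differ).
#' @param n_perm permutations (or bootstrap draws).
#' @param seed integer seed.
#' @param method `"null_perm"` (default) or `"bootstrap"`.
#' @return a [resampling_result()] with extra fields `significant`,
#'   `n_pairs`, `g1`, `g2`.
#' @export
cross_group_correlation_ci <- function(x, y, groups, g1, g2, n_perm = 1000,
                                       seed, method = c("null_perm",
                                                        "bootstrap")) {
  method <- match.arg(method)
  if (identical(g1, g2)) stop("g1 and g2 must be different habitats")
  y <- align_dist(x, y)
  pops1 <- names(groups)[groups == g1]
  pops2 <- names(groups)[groups == g2]
  if (length(pops1) < 2 || length(pops2) < 2)
    stop("need at least 2 populations per group")
  if (!all(c(pops1, pops2) %in% rownames(x)))
    stop("populations missing from distance matrix")
  idx <- between_pairs(rownames(x), pops1, pops2)
  if (nrow(idx) < 3) stop("fewer than 3 between-group pairs")
  pair_r <- function(aa, bb) {
    ij <- cbind(aa, bb)
    stats::cor(x[ij], y[ij])
  }
  obs <- pair_r(idx$a, idx$b)
  union_idx <- match(c(pops1, pops2), rownames(x))
  n1 <- length(pops1)
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      if (method == "null_perm") {
        perm <- sample(union_idx)
        ij <- expand.grid(a = perm[seq_len(n1)], b = perm[-seq_len(n1)])
        pair_r(ij$a, ij$b)
      } else {
        take <- sample.int(nrow(idx), replace = TRUE)
        pair_r(idx$a[take], idx$b[take])
      }
    }, numeric(1))
  })
  res <- resampling_result(observed = obs, replicates = reps, seed = seed,
                           method = method, g1 = g1, g2 = g2,
                           n_pairs = nrow(idx))
  res$significant <- obs < res$ci_low || obs > res$ci_high
  res
}

#' Enumerate habitat pair categories
#'
#' Builds the full family of population-pair categories: one within-habitat
#' set per habitat present, every between-habitat set (rural-urban and
#' urban-urban), and ALL (every unordered pair).
#'
#' @param groups named character vector mapping population id to habitat
#'   (RA / UA / UP / UR).
#' @return named list of `pair_set` objects: `list(label, pairs)` with
#'   `pairs` a data frame of unordered (popA, popB) pairs.
#' @export
build_pair_sets <- function(groups) {
  bad <- setdiff(unique(groups), habitat_levels())
  if (length(bad)) stop("unknown habitat code(s): ", paste(bad, collapse = ", "))
  pops_of <- function(h) names(groups)[groups == h]
  make <- function(label, pairs) {
    structure(list(label = label, pairs = pairs), class = "pair_set")
  }
  within_set <- function(h) {
    p <- pops_of(h)
    if (length(p) < 2) return(NULL)
    cmb <- utils::combn(p, 2)
    make(h, data.frame(popA = cmb[1, ], popB = cmb[2, ]))
  }
  between_set <- function(h1, h2) {
    p1 <- pops_of(h1); p2 <- pops_of(h2)
    if (!length(p1) || !length(p2)) return(NULL)
    g <- expand.grid(popA = p1, popB = p2, stringsAsFactors = FALSE)
    make(paste0(h1, "_", h2), g)
  }
  habs <- intersect(habitat_levels(), unique(groups))
  sets <- c(lapply(habs, within_set),
            list(between_set("RA", "UA"), between_set("RA", "UP"),
                 between_set("RA", "UR"), between_set("UA", "UP"),
                 between_set("UA", "UR"), between_set("UP", "UR")))
  sets <- Filter(Negate(is.null), sets)
  all_cmb <- utils::combn(names(groups), 2)
  sets <- c(sets, list(make("ALL", data.frame(popA = all_cmb[1, ],
                                              popB = all_cmb[2, ]))))
  stats::setNames(sets, vapply(sets, `[[`, character(1), "label"))
}

#' Resampling comparison of distances across pair categories
#'
#' Per replicate, one pair is drawn uniformly (with replacement across
#' replicates) from each category and its distance recorded; per category
#' the mean and 2.5/97.5 percentiles of the recorded values are reported,
#' along with the matrix of CI overlaps between categories.
#'
#' @param d a `dist_matrix`.
#' @param categories list of `pair_set`s from [build_pair_sets()].
#' @param n_reps replicates.
#' @param seed integer seed.
#' @return list with `summary` (data frame: category, n_pairs, mean,
#'   ci_low, ci_high), `results` (per-category [resampling_result()]) and
#'   `overlap` (logical matrix of CI overlap).
#' @export
habitat_pair_resample <- function(d, categories, n_reps = 1000, seed) {
  if (!length(categories)) stop("no pair categories supplied")
  values_of <- function(ps) {
    if (!nrow(ps$pairs)) stop("empty pair category: ", ps$label)
    v <- d[cbind(ps$pairs$popA, ps$pairs$popB)]
    if (any(!is.finite(v))) {
      warning(sum(!is.finite(v)), " non-finite distance(s) excluded from ",
              ps$label)
      v <- v[is.finite(v)]
      if (!length(v)) stop("no finite distances in category ", ps$label)
    }
    v
  }
  names(categories) <- vapply(categories, `[[`, character(1), "label")
  results <- withr::with_seed(seed, {
    lapply(categories, function(ps) {
      v <- values_of(ps)
      draws <- v[sample.int(length(v), n_reps, replace = TRUE)]
      resampling_result(observed = mean(draws), replicates = draws,
                        seed = seed, label = ps$label,
                        n_pairs = length(v))
    })
  })
  summary <- data.frame(
    category = names(results),
    n_pairs = vapply(results, `[[`, numeric(1), "n_pairs"),
    mean = vapply(results, `[[`, numeric(1), "observed"),
    ci_low = vapply(results, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(results, `[[`, numeric(1), "ci_high"),
    row.names = NULL)
  k <- nrow(summary)
  overlap <- matrix(TRUE, k, k, dimnames = list(summary$category,
                                                summary$category))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    overlap[i, j] <- summary$ci_low[i] <= summary$ci_high[j] &&
      summary$ci_low[j] <= summary$ci_high[i]
  }
  list(summary = summary, results = results, overlap = overlap)
}
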