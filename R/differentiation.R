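# loci with defined frequencies in both populations of a pair
shared_loci <- function(f, popA, popB) {
  a <- match(popA, f$pops)
  b <- match(popB, f$pops)
  if (is.na(a) || is.na(b))
    stop("unknown population id: ", popA[is.na(a)], popB[is.na(b)])
  ok <- !is.na(f$p_alt[a, ]) & !is.na(f$p_alt[b, ])
  if (!any(ok)) stop("populations ", popA, " and ", popB,
                     " share no locus with defined frequencies")
  list(a = a, b = b, ok = ok)
}

#' Nei's (1972) standard genetic distance between two populations
#'
#' `D = -ln I` with `I = J_AB / sqrt(J_A J_B)`, where `J_A`, `J_B` and
#' `J_AB` are the means over shared loci of the within- and
#' between-population probabilities of allele identity
#' (`sum(p^2)`, `sum(q^2)`, `sum(p q)`). Loci with undefined frequencies in
#' either population are excluded pairwise. When the populations share no
#' alleles (`I = 0`) the distance is `Inf` (sentinel, reported downstream).
#'
#' @param f an `allele_freq_table` (see [allele_frequencies()]).
#' @param popA,popB population ids.
#' @return a non-negative number, possibly `Inf`.
#' @export
nei_distance <- function(f, popA, popB) {
  s <- shared_loci(f, popA, popB)
  pa <- f$p_alt[s$a, s$ok]
  pb <- f$p_alt[s$b, s$ok]
  jA <- mean(pa^2 + (1 - pa)^2)
  jB <- mean(pb^2 + (1 - pb)^2)
  jAB <- mean(pa * pb + (1 - pa) * (1 - pb))
  if (jAB == 0) return(Inf)
  -log(jAB / sqrt(jA * jB))
}

#' Pairwise fixation index between two populations
#'
#' The default (`method = "nei"`) is the Nei/G_ST-style multilocus
#' estimator `F_ST = sum_l(H_T - H_S) / sum_l H_T` (ratio of locus sums),
#' with `H_S` the mean of the two within-population expected
#' heterozygosities (plain `2pq`) and `H_T` computed from the unweighted
#' mean allele frequency. `method = "wc"` gives the Weir-Cockerham (1984)
#' theta, which additionally uses sample sizes and observed heterozygote
#' counts. If `H_T = 0` at every shared locus (no variation) the index is
#' undefined; 0 is returned with a warning.
#'
#' @inheritParams nei_distance
#' @param method `"nei"` (default) or `"wc"`.
#' @return a number, typically in `[0, 1]` (the Weir-Cockerham estimator
#'   can be slightly negative).
#' @export
fst_pairwise <- function(f, popA, popB, method = c("nei", "wc")) {
  method <- match.arg(method)
  s <- shared_loci(f, popA, popB)
  pa <- f$p_alt[s$a, s$ok]
  pb <- f$p_alt[s$b, s$ok]
  if (method == "nei") {
    hs <- (2 * pa * (1 - pa) + 2 * pb * (1 - pb)) / 2
    pbar <- (pa + pb) / 2
    ht <- 2 * pbar * (1 - pbar)
    if (sum(ht) == 0) {
      warning("no variation at any shared locus; F_ST undefined, reporting 0")
      return(0)
    }
    return(sum(ht - hs) / sum(ht))
  }
  # Weir & Cockerham 1984 theta, r = 2 populations
  ni <- cbind(f$n_ind[s$a, s$ok], f$n_ind[s$b, s$ok])
  pi <- cbind(pa, pb)
  hi <- cbind(f$het[s$a, s$ok] / f$n_ind[s$a, s$ok],
              f$het[s$b, s$ok] / f$n_ind[s$b, s$ok])
  r <- 2
  nbar <- rowMeans(ni)
  nc <- (r * nbar - rowSums(ni^2) / (r * nbar)) / (r - 1)
  pbar <- rowSums(ni * pi) / (r * nbar)
  s2 <- rowSums(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- rowSums(ni * hi) / (r * nbar)
  ok <- nbar > 1 & nc > 0
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  num <- sum(a[ok])
  den <- sum((a + b + cc)[ok])
  if (den == 0) {
    warning("no variation at any shared locus; theta undefined, reporting 0")
    return(0)
  }
  num / den
}

#' Pairwise genetic distance / differentiation matrix
#'
#' @param f an `allele_freq_table`.
#' @param metric `"nei"` (Nei 1972 D) or `"fst"`.
#' @param fst_method passed to [fst_pairwise()] when `metric = "fst"`.
#' @return a `dist_matrix` (labelled symmetric matrix, zero diagonal).
#'   Infinite Nei distances propagate as `Inf` with a warning.
#' @export
distance_matrix <- function(f, metric = c("nei", "fst"),
                            fst_method = c("nei", "wc")) {
  metric <- match.arg(metric)
  fst_method <- match.arg(fst_method)
  pops <- f$pops
  if (length(pops) < 2) stop("need at least two populations")
  m <- matrix(0, length(pops), length(pops), dimnames = list(pops, pops))
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1)) {
    v <- switch(metric,
                nei = nei_distance(f, pops[i], pops[j]),
                fst = fst_pairwise(f, pops[i], pops[j], method = fst_method))
    m[i, j] <- m[j, i] <- v
  }
  if (any(is.infinite(m)))
    warning(sum(is.infinite(m)) / 2,
            " population pair(s) have infinite Nei distance (no shared alleles)")
  dist_matrix_obj(m, kind = metric)
}

#' Principal coordinate analysis of a distance matrix
#'
#' Gower double-centering and eigendecomposition, delegated to
#' [ape::pcoa()]; axes with positive eigenvalues are retained. Percent
#' variance of axis k is `100 * lambda_k / sum(positive lambda)`, and the
#' relative mass of negative eigenvalues is reported (Bray-Curtis and other
#' semimetric inputs are expected to produce some).
#'
#' @param d a `dist_matrix` with finite entries (resolve or drop infinite
#'   sentinels first).
#' @param correction `"none"`, `"lingoes"` or `"cailliez"`.
#' @return list of class `pcoa_result`: `eigenvalues` (all, descending),
#'   `coordinates` (populations x positive axes, scaled by sqrt(lambda)),
#'   `percent_variance`, `negative_mass`.
#' @export
pcoa_ordination <- function(d, correction = c("none", "lingoes", "cailliez")) {
  correction <- match.arg(correction)
  if (any(!is.finite(d)))
    stop("distance matrix contains non-finite entries; drop those pairs first")
  if (all(d == 0)) {
    # degenerate: identical points; centered matrix is zero
    n <- nrow(d)
    return(structure(list(
      eigenvalues = rep(0, n - 1),
      coordinates = matrix(numeric(0), n, 0,
                           dimnames = list(rownames(d), NULL)),
      percent_variance = numeric(0), negative_mass = 0,
      correction = correction), class = "pcoa_result"))
  }
  res <- ape::pcoa(stats::as.dist(d),
                   correction = if (correction == "none") "none" else correction)
  # with a correction applied, ape reports corrected eigenvalues in column 1
  ev <- res$values[, 1]
  pos <- ev > .Machine$double.eps * max(abs(ev)) * nrow(res$values)
  coords <- res$vectors[, seq_len(sum(pos)), drop = FALSE]
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(
    eigenvalues = ev,
    coordinates = coords,
    percent_variance = 100 * ev[pos] / sum(ev[pos]),
    negative_mass = sum(abs(ev[ev < 0])) / sum(abs(ev)),
    correction = correction), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  k <- min(4, length(x$percent_variance))
  cat(sprintf("PCoA: %d positive axes; first %d explain %s%% of variance\n",
              ncol(x$coordinates), k,
              paste(sprintf("%.2f", x$percent_variance[seq_len(k)]),
                    collapse = " / ")))
  invisible(x)
}
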