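# in-code fixtures shared across test files

# genotype matrix from a plain integer matrix, individuals auto-named
toy_genotypes <- function(m, pops) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("i%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("L%02d", seq_len(ncol(m)))
  genotype_matrix(m, setNames(pops, rownames(m)))
}

# random genotype matrix with missingness, for property tests
random_genotypes <- function(n_ind, n_loci, n_pops = 2, missing = 0.2,
                             seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(sample(0:2, n_ind * n_loci, replace = TRUE), n_ind, n_loci)
    m[runif(length(m)) < missing] <- NA_integer_
    toy_genotypes(m, rep(sprintf("p%d", seq_len(n_pops)),
                         length.out = n_ind))
  })
}

# allele-frequency table built directly from per-population alt-allele
# counts (rows = pops); n = gene copies, het defaults to HWE-free zeros
freq_table <- function(alt, n, het = NULL) {
  pops <- rownames(alt)
  if (is.null(pops)) pops <- sprintf("p%d", seq_len(nrow(alt)))
  loci <- colnames(alt)
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(ncol(alt)))
  dimnames(alt) <- dimnames(n) <- list(pops, loci)
  if (is.null(het)) het <- matrix(0, nrow(alt), ncol(alt), dimnames = dimnames(alt))
  structure(list(pops = pops, loci = loci, n = n, alt = alt, het = het,
                 n_ind = n / 2,
                 p_alt = ifelse(n > 0, alt / n, NA_real_)),
            class = "allele_freq_table")
}

# random labelled symmetric matrix with zero diagonal
random_dist <- function(n, labels = sprintf("p%02d", seq_len(n)), seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(labels, labels)
    m
  })
}

# minimal metadata table for n populations
toy_metadata <- function(n = 4, habitats = rep(c("RA", "UA", "UP", "UR"),
                                               length.out = n),
                         landcover = TRUE, seed = 1) {
  withr::with_seed(seed, {
    df <- data.frame(pop_id = sprintf("p%02d", seq_len(n)),
                     habitat = habitats,
                     lat = runif(n, 34.7, 35.1),
                     lon = runif(n, 135.25, 135.8))
    if (landcover) {
      for (r in c(250, 500, 1000)) {
        a <- pi * r^2
        fr <- matrix(rgamma(4 * n, 2), n, 4)
        fr <- fr / rowSums(fr)
        df[paste0(c("developed", "agricultural", "forest", "grassland"),
                  "_", r)] <- fr * a
      }
    }
    validate_metadata(df)
  })
}
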