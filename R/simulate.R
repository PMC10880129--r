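#' Define a forward-time simulation scenario
#'
#' Parameterises the forward-time Wright-Fisher simulator with partial
#' selfing, habitat-structured migration and optional founder events. The
#' simulator is hybrid: migration acts on population allele frequencies
#' (building the outcrossing gamete pool), while reproduction is
#' individual-based so that selfing generates the homozygote excess the
#' diversity statistics must detect. Offspring are selfed with probability
#' `selfing` (gametes drawn from one random parent) and otherwise formed
#' from two independent gametes of the post-migration pool.
#'
#' @param n_pops number of populations.
#' @param habitat_of habitat per population (RA / UA / UP / UR), recycled.
#' @param pop_ids population ids (default `pop01`, ...).
#' @param coords optional matrix/data frame with columns `lat`, `lon`; if
#'   `NULL`, drawn uniformly in `bbox` with UA sites contracted toward the
#'   centre (urban agricultural remnants cluster in the urban core).
#' @param bbox bounding box `c(lat_min, lat_max, lon_min, lon_max)`;
#'   default spans roughly 66 km diagonally, a megacity-scale extent.
#' @param landcover_means list per habitat of mean land-cover fractions
#'   (developed, agricultural, forest, grassland).
#' @param landcover_conc Dirichlet-like concentration of land-cover noise
#'   (larger = less variable).
#' @param n_loci number of unlinked biallelic loci.
#' @param N diploid population size (scalar, recycled per population).
#' @param selfing selfing rate `s` in `[0, 1]`; equilibrium
#'   `F_IS = s / (2 - s)`.
#' @param migration list: `model` one of `"distance"`, `"island"`,
#'   `"none"`; `m0` baseline emigration rate; `lambda_geo_km` e-folding
#'   geographic distance; `lambda_env` e-folding Bray-Curtis landscape
#'   distance (`Inf` disables the landscape term).
#' @param founders optional data frame with columns `pop`, `source`,
#'   `t_f` (generation of the event), `n_f` (founder count, `<= N`).
#' @param generations number of generations to run.
#' @param missing_rate mean per-genotype missingness applied to the final
#'   sample.
#' @param missing_locus_sd,missing_sample_sd logit-scale standard
#'   deviations of per-locus and per-individual missingness effects.
#'   Zero (the default) gives i.i.d. missingness; positive values mimic
#'   reduced-representation sequencing, where dropout concentrates in
#'   poorly genotyped loci and low-quality samples. The mean rate is
#'   rescaled back to `missing_rate` after the effects are drawn.
#' @param samples_per_pop individuals sampled per population: a scalar, a
#'   vector per population, or a length-2 range drawn uniformly per
#'   population (default `c(3, 7)`, the field design).
#' @param init_freq initial alternate-allele frequency: `NULL` for
#'   Beta(0.8, 0.8) draws (a site-frequency spectrum whose common variants
#'   survive a 1% MAF filter), a scalar, or a vector per locus.
#' @param seed default seed used by [simulate_scenario()].
#' @return list of class `sim_scenario`.
#' @export
sim_scenario <- function(n_pops = 24,
                         habitat_of = rep(c("RA", "UA", "UP", "UR"),
                                          length.out = n_pops),
                         pop_ids = sprintf("pop%02d", seq_len(n_pops)),
                         coords = NULL,
                         bbox = c(34.70, 35.10, 135.25, 135.80),
                         landcover_means = default_landcover_means(),
                         landcover_conc = 60,
                         n_loci = 600,
                         N = 100,
                         selfing = 0.9,
                         migration = list(model = "distance", m0 = 0.05,
                                          lambda_geo_km = 15,
                                          lambda_env = Inf),
                         founders = NULL,
                         generations = 50,
                         missing_rate = 0.25,
                         missing_locus_sd = 0,
                         missing_sample_sd = 0,
                         samples_per_pop = c(3, 7),
                         init_freq = NULL,
                         seed = 1L) {
  habitat_of <- rep(habitat_of, length.out = n_pops)
  stopifnot(length(pop_ids) == n_pops, !anyDuplicated(pop_ids),
            all(habitat_of %in% habitat_levels()),
            selfing >= 0, selfing <= 1,
            missing_rate >= 0, missing_rate <= 1,
            missing_locus_sd >= 0, missing_sample_sd >= 0,
            n_loci >= 1, generations >= 0)
  N <- rep(N, length.out = n_pops)
  if (identical(founders, "nearest")) {
    # resolved against the realised geography inside simulate_scenario()
    if (!any(habitat_of %in% c("UP", "UR")) ||
        !any(habitat_of %in% c("RA", "UA")))
      stop("\"nearest\" founders need UP/UR populations and RA/UA sources")
  } else if (!is.null(founders)) {
    stopifnot(all(c("pop", "source", "t_f", "n_f") %in% names(founders)),
              all(founders$pop %in% pop_ids))
    if (!all(founders$source %in% pop_ids))
      stop("founder source population(s) not in scenario: ",
           paste(setdiff(founders$source, pop_ids), collapse = ", "))
    if (any(founders$pop == founders$source))
      stop("a population cannot found itself")
    if (any(founders$n_f > N[match(founders$pop, pop_ids)]))
      stop("founder count exceeds population size")
    if (any(founders$t_f < 1 | founders$t_f > generations))
      stop("founder event outside the simulated generations")
  }
  structure(list(n_pops = n_pops, habitat_of = habitat_of, pop_ids = pop_ids,
                 coords = coords, bbox = bbox,
                 landcover_means = landcover_means,
                 landcover_conc = landcover_conc,
                 n_loci = n_loci, N = N, selfing = selfing,
                 migration = migration, founders = founders,
                 generations = generations, missing_rate = missing_rate,
                 missing_locus_sd = missing_locus_sd,
                 missing_sample_sd = missing_sample_sd,
                 samples_per_pop = samples_per_pop, init_freq = init_freq,
                 seed = seed),
            class = "sim_scenario")
}

#' Default mean land-cover fractions per habitat
#'
#' Developed / agricultural / forest / grassland fractions typical of the
#' four habitat classes: rural agricultural land is farmland-dominated,
#' urban agricultural remnants sit in built matrix, parks add green cover
#' inside the city, roadsides are development-dominated.
#'
#' @return named list of length-4 fraction vectors.
#' @export
default_landcover_means <- function() {
  list(RA = c(developed = 0.15, agricultural = 0.55, forest = 0.20,
              grassland = 0.10),
       UA = c(developed = 0.50, agricultural = 0.35, forest = 0.05,
              grassland = 0.10),
       UP = c(developed = 0.55, agricultural = 0.05, forest = 0.25,
              grassland = 0.15),
       UR = c(developed = 0.80, agricultural = 0.05, forest = 0.05,
              grassland = 0.10))
}

# Dirichlet-like land-cover fractions, one draw per population x radius
draw_landcover <- function(habitat, conc, means) {
  mu <- means[[habitat]]
  gshape <- conc * mu
  g <- stats::rgamma(length(mu), shape = pmax(gshape, 1e-3))
  stats::setNames(g / sum(g), names(mu))
}

simulate_coords <- function(scn) {
  lat <- stats::runif(scn$n_pops, scn$bbox[1], scn$bbox[2])
  lon <- stats::runif(scn$n_pops, scn$bbox[3], scn$bbox[4])
  ua <- scn$habitat_of == "UA"
  if (any(ua)) {
    # UA sites contracted toward the regional centre: urban agricultural
    # remnants are geographically clustered relative to rural farmland
    lat[ua] <- mean(scn$bbox[1:2]) + 0.45 * (lat[ua] - mean(scn$bbox[1:2]))
    lon[ua] <- mean(scn$bbox[3:4]) + 0.45 * (lon[ua] - mean(scn$bbox[3:4]))
  }
  cbind(lat = lat, lon = lon)
}

simulate_metadata <- function(scn) {
  coords <- scn$coords
  if (is.null(coords)) coords <- simulate_coords(scn)
  meta <- data.frame(pop_id = scn$pop_ids, habitat = scn$habitat_of,
                     lat = coords[, "lat"], lon = coords[, "lon"])
  for (r in landcover_radii()) {
    area <- pi * r^2
    fr <- t(vapply(scn$habitat_of, draw_landcover,
                   numeric(4), conc = scn$landcover_conc,
                   means = scn$landcover_means))
    for (cl in landcover_classes())
      meta[[paste0(cl, "_", r)]] <- fr[, cl] * area
  }
  validate_metadata(meta)
}

build_migration_matrix <- function(scn, geo_km, bc) {
  n <- scn$n_pops
  mig <- scn$migration
  M <- matrix(0, n, n, dimnames = list(scn$pop_ids, scn$pop_ids))
  if (is.null(mig) || mig$model == "none" || scn$n_pops == 1) return(M)
  if (mig$model == "island") {
    M[] <- mig$m0 / (n - 1)
  } else {
    M <- mig$m0 * exp(-geo_km / mig$lambda_geo_km)
    if (is.finite(mig$lambda_env)) M <- M * exp(-bc / mig$lambda_env)
  }
  diag(M) <- 0
  rs <- rowSums(M)
  over <- rs > 0.8
  if (any(over)) M[over, ] <- M[over, ] * (0.8 / rs[over])
  M
}

# one generation of reproduction for one population's genotype matrix
reproduce_pop <- function(G, N_off, s, pool_freq) {
  L <- ncol(G)
  selfed <- stats::runif(N_off) < s
  n_self <- sum(selfed)
  n_out <- N_off - n_self
  out <- matrix(0L, N_off, L)
  if (n_self) {
    parent <- sample.int(nrow(G), n_self, replace = TRUE)
    child <- G[parent, , drop = FALSE]
    het <- which(child == 1L)
    if (length(het)) child[het] <- stats::rbinom(length(het), 2, 0.5)
    out[seq_len(n_self), ] <- child
  }
  if (n_out) {
    out[n_self + seq_len(n_out), ] <-
      matrix(stats::rbinom(n_out * L, 2, rep(pool_freq, each = n_out)),
             n_out, L)
  }
  out
}

#' Run a forward-time simulation
#'
#' Per generation and population: (1) optional founder event replaces the
#' population with `n_f` individuals drawn from its source; (2) the
#' outcrossing gamete pool is the migration-weighted mixture of population
#' allele frequencies, `p_i' = (1 - sum_j m_ij) p_i + sum_j m_ij p_j`;
#' (3) each of `N` offspring is selfed with probability `s` (gametes from
#' one random parent) or outcrossed (two independent Bernoulli gametes
#' from the pool, i.e. binomial(2, p') dosage), which realises binomial
#' drift at size `N`. Finally the stated number of individuals per
#' population is sampled without replacement and i.i.d. missingness is
#' applied.
#'
#' @param scn a [sim_scenario()].
#' @param seed integer seed (defaults to the scenario's).
#' @return list with `genotypes` (a [genotype_matrix()]), `meta` (a
#'   `pop_meta` data frame), and `truth` (parameters, migration matrix and
#'   realised final allele frequencies).
#' @export
simulate_scenario <- function(scn, seed = scn$seed) {
  stopifnot(inherits(scn, "sim_scenario"))
  withr::with_seed(seed, {
    meta <- simulate_metadata(scn)
    geo <- geographic_distance(meta)
    bc <- landscape_distance(meta, radius = 500)
    M <- build_migration_matrix(scn, geo, bc)

    p0 <- scn$init_freq
    if (is.null(p0)) p0 <- stats::rbeta(scn$n_loci, 0.8, 0.8)
    p0 <- rep(p0, length.out = scn$n_loci)

    G <- lapply(seq_len(scn$n_pops), function(i) {
      matrix(stats::rbinom(scn$N[i] * scn$n_loci, 2, rep(p0, each = scn$N[i])),
             scn$N[i], scn$n_loci)
    })

    founders <- scn$founders
    if (identical(founders, "nearest"))
      founders <- nearest_source_founders(scn, geo)
    for (t in seq_len(scn$generations)) {
      if (!is.null(founders)) {
        ev <- founders[founders$t_f == t, , drop = FALSE]
        for (k in seq_len(nrow(ev))) {
          i <- match(ev$pop[k], scn$pop_ids)
          src <- match(ev$source[k], scn$pop_ids)
          take <- sample.int(nrow(G[[src]]), ev$n_f[k], replace = FALSE)
          G[[i]] <- G[[src]][take, , drop = FALSE]
        }
      }
      P <- do.call(rbind, lapply(G, function(g) colMeans(g) / 2))
      pool <- (1 - rowSums(M)) * P + M %*% P
      for (i in seq_len(scn$n_pops))
        G[[i]] <- reproduce_pop(G[[i]], scn$N[i], scn$selfing, pool[i, ])
    }

    n_samp <- scn$samples_per_pop
    if (length(n_samp) == 2 && scn$n_pops != 2) {
      n_samp <- sample(seq(n_samp[1], n_samp[2]), scn$n_pops, replace = TRUE)
    } else n_samp <- rep(n_samp, length.out = scn$n_pops)
    if (any(n_samp > scn$N))
      stop("sample size exceeds population size")

    sampled <- lapply(seq_len(scn$n_pops), function(i) {
      G[[i]][sample.int(nrow(G[[i]]), n_samp[i]), , drop = FALSE]
    })
    geno <- do.call(rbind, sampled)
    if (scn$missing_rate > 0) {
      a <- stats::rnorm(ncol(geno), 0, scn$missing_locus_sd)
      b <- stats::rnorm(nrow(geno), 0, scn$missing_sample_sd)
      rate <- stats::plogis(stats::qlogis(scn$missing_rate) + outer(b, a, "+"))
      rate <- pmin(rate * scn$missing_rate / mean(rate), 0.95)
      drop <- stats::runif(length(geno)) < rate
      geno[drop] <- NA_integer_
    }
    ind_pop <- rep(scn$pop_ids, n_samp)
    ids <- paste0(ind_pop, "_", unlist(lapply(n_samp, seq_len)))
    dimnames(geno) <- list(ids, sprintf("L%04d", seq_len(scn$n_loci)))
    g <- genotype_matrix(geno, stats::setNames(ind_pop, ids))

    final_freq <- do.call(rbind, lapply(G, function(gg) colMeans(gg) / 2))
    dimnames(final_freq) <- list(scn$pop_ids, colnames(geno))
    list(genotypes = g, meta = meta,
         truth = list(scenario = scn, seed = seed, migration = M,
                      founders = founders, init_freq = p0,
                      final_freq = final_freq,
                      samples_per_pop = stats::setNames(n_samp, scn$pop_ids)))
  })
}
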