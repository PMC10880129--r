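tiny_scn <- function(...) {
  args <- list(n_pops = 3, habitat_of = c("RA", "UA", "UP"), n_loci = 40,
               N = 30, generations = 5, missing_rate = 0.1,
               samples_per_pop = 5, seed = 2)
  args[names(list(...))] <- list(...)
  do.call(sim_scenario, args)
}

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- simulate_scenario(tiny_scn())
  b <- simulate_scenario(tiny_scn())
  expect_identical(a$genotypes$geno, b$genotypes$geno)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$final_freq, b$truth$final_freq)
  c_ <- simulate_scenario(tiny_scn(), seed = 99)
  expect_false(identical(a$genotypes$geno, c_$genotypes$geno))
})

test_that("realized missingness is within 2 points of nominal at scale", {
  scn <- sim_scenario(n_pops = 20, n_loci = 600, N = 20, generations = 2,
                      missing_rate = 0.25, samples_per_pop = 5, seed = 5)
  sim <- simulate_scenario(scn)
  expect_equal(dim(sim$genotypes$geno), c(100, 600))
  expect_lt(abs(mean(is.na(sim$genotypes$geno)) - 0.25), 0.02)
})

test_that("complete selfing drives observed heterozygosity to zero", {
  scn <- sim_scenario(n_pops = 1, habitat_of = "RA", n_loci = 100, N = 50,
                      selfing = 1, generations = 30, missing_rate = 0,
                      samples_per_pop = 25,
                      migration = list(model = "none"), seed = 3)
  sim <- simulate_scenario(scn)
  ho <- observed_heterozygosity(sim$genotypes)$per_population
  expect_lt(unname(ho), 0.02)
})

test_that("isolated populations fix independently (F_ST -> 1)", {
  scn <- sim_scenario(n_pops = 2, habitat_of = c("RA", "RA"), n_loci = 150,
                      N = 10, selfing = 0.5, generations = 300,
                      missing_rate = 0, samples_per_pop = c(10, 10),
                      migration = list(model = "none"), seed = 4)
  sim <- simulate_scenario(scn)
  f <- allele_frequencies(sim$genotypes)
  expect_gt(fst_pairwise(f, "pop01", "pop02"), 0.8)
})

test_that("global allele-frequency mean is a martingale", {
  finals <- vapply(1:200, function(s) {
    scn <- sim_scenario(n_pops = 1, habitat_of = "RA", n_loci = 1, N = 100,
                        selfing = 0, generations = 10, missing_rate = 0,
                        samples_per_pop = 5, init_freq = 0.5,
                        migration = list(model = "none"), seed = s)
    simulate_scenario(scn)$truth$final_freq[1, 1]
  }, numeric(1))
  expect_gt(mean(finals), 0.45)
  expect_lt(mean(finals), 0.55)
})

test_that("scenario construction validates founder events and sampling", {
  expect_error(tiny_scn(founders = data.frame(pop = "pop01",
                                              source = "nope",
                                              t_f = 2, n_f = 5)),
               "source")
  expect_error(tiny_scn(founders = data.frame(pop = "pop01",
                                              source = "pop01",
                                              t_f = 2, n_f = 5)),
               "itself")
  expect_error(tiny_scn(founders = data.frame(pop = "pop01",
                                              source = "pop02",
                                              t_f = 2, n_f = 500)),
               "exceeds")
  expect_error(simulate_scenario(tiny_scn(samples_per_pop = 200)),
               "sample size")
  expect_error(scenario_library("nope"))
})

test_that("founder events bottleneck the founded population", {
  scn <- tiny_scn(n_pops = 2, habitat_of = c("RA", "UP"), N = 100,
                  n_loci = 200, generations = 10, missing_rate = 0,
                  samples_per_pop = c(20, 20),
                  migration = list(model = "none"),
                  founders = data.frame(pop = "pop02", source = "pop01",
                                        t_f = 8, n_f = 2))
  sim <- simulate_scenario(scn)
  ar <- allelic_richness(allele_frequencies(sim$genotypes))$per_population
  expect_lt(ar[["pop02"]], ar[["pop01"]])
})

test_that("scenario library emits valid, named scenarios", {
  for (nm in c("study", "ibd", "island", "habitat_divergence",
               "founder_parks", "null")) {
    scn <- scenario_library(nm, seed = 1)
    expect_s3_class(scn, "sim_scenario")
    expect_identical(scn$name, nm)
  }
  scn <- scenario_library("study", seed = 1)
  expect_equal(scn$n_pops, 24)
  expect_equal(as.vector(table(scn$habitat_of)[c("RA", "UA", "UP", "UR")]),
               c(8, 5, 5, 6))
  expect_equal(scn$n_loci, 600)
})

test_that("simulated metadata passes validation and respects geography", {
  sim <- simulate_scenario(scenario_library("study", seed = 3,
                                            n_loci = 20, generations = 2))
  expect_s3_class(sim$meta, "pop_meta")
  d <- geographic_distance(sim$meta)
  expect_lt(max(d), 80)   # megacity extent, tens of km
  # UA sites are contracted toward the centre relative to RA sites
  ua <- sim$meta$habitat == "UA"; ra <- sim$meta$habitat == "RA"
  expect_lt(mean(d[ua, ua][upper.tri(d[ua, ua])]),
            mean(d[ra, ra][upper.tri(d[ra, ra])]))
})
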