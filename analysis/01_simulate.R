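#!/usr/bin/env Rscript
# Stage 1: generate the study-scale data set.
#
# Simulates 24 populations (8 RA, 5 UA, 5 UP, 6 UR) of a highly selfing
# annual at megacity extent: 600 biallelic loci, distance- and
# landscape-structured migration, 3-7 sampled individuals per population,
# ~25% structured missingness. Writes the genotype CSV, the population
# metadata (coordinates + land cover at 250/500/1000 m) and the simulation
# truth record.

library(urbanpopgen)

seed <- 1L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sim <- simulate_scenario(scenario_library("study", seed = seed))

write_genotype_csv(sim$genotypes, file.path(out, "genotypes.csv"))
write_metadata(sim$meta, file.path(out, "metadata.csv"))
jsonlite::write_json(
  list(seed = seed, scenario = "study",
       n_pops = sim$truth$scenario$n_pops,
       n_loci = sim$truth$scenario$n_loci,
       selfing = sim$truth$scenario$selfing,
       generations = sim$truth$scenario$generations,
       samples_per_pop = as.list(sim$truth$samples_per_pop)),
  file.path(out, "truth.json"), auto_unbox = TRUE, pretty = TRUE)

cat(sprintf("simulated %d individuals x %d loci across %d populations\n",
            length(individual_ids(sim$genotypes)),
            length(locus_ids(sim$genotypes)),
            length(population_ids(sim$genotypes))))
cat(sprintf("realized missingness: %.1f%%\n",
            100 * mean(is.na(sim$genotypes$geno))))
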