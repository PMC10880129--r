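#!/usr/bin/env Rscript
# Stage 2: sample and locus filtering.
#
# Applies the genotype-matrix filters used at the 'populations' stage of a
# Stacks workflow: individuals with > 40% missing calls are excluded, then
# loci are kept when call rate >= 0.8, global minor-allele frequency
# >= 0.01 and observed heterozygosity <= 0.95.

library(urbanpopgen)

g <- read_genotype_csv("results/data/genotypes.csv")
cfg <- filter_config()  # (0.01, 0.95, 0.8, 0.40)

res <- filter_genotypes(g, cfg)
dir.create("results", showWarnings = FALSE)
write_genotype_csv(res$genotypes, "results/genotypes_filtered.csv")
write_filter_report(res$report, "results/filter_report.json")

cat(sprintf("samples: %d in, %d removed (>%g%% missing)\n",
            res$report$samples$n_in, res$report$samples$n_removed,
            100 * cfg$max_sample_missing))
cat(sprintf("loci: %d in, removed by coverage/maf/het = %d/%d/%d, %d retained\n",
            res$report$loci$n_in,
            res$report$loci$n_removed[["coverage"]],
            res$report$loci$n_removed[["maf"]],
            res$report$loci$n_removed[["het"]],
            length(res$report$loci$retained)))
cat(sprintf("coverage rate of retained matrix: %.1f%%\n",
            100 * mean(!is.na(res$genotypes$geno))))
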