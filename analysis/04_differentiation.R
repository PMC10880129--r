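#!/usr/bin/env Rscript
# Stage 4: pairwise genetic differentiation and ordination.
#
# Builds the pairwise Nei (1972) genetic distance and F_ST matrices,
# checks their concordance with a Mantel test (they should rank pairs
# almost identically, justifying the use of Nei D downstream), and runs a
# principal coordinate analysis of the Nei matrix.

library(urbanpopgen)

seed <- 1L
g <- read_genotype_csv("results/genotypes_filtered.csv")
f <- allele_frequencies(g)

d_nei <- distance_matrix(f, "nei")
d_fst <- distance_matrix(f, "fst")
write_dist_tsv(d_nei, "results/dist_nei.tsv")
write_dist_tsv(d_fst, "results/dist_fst.tsv")

m <- mantel_test(d_nei, d_fst, n_perm = 999, seed = seed)
cat(sprintf("Nei D vs F_ST concordance: Mantel r = %.3f, p = %.3g\n",
            m$observed, m$p))

pco <- pcoa_ordination(d_nei)
write.csv(data.frame(axis = seq_along(pco$percent_variance),
                     percent_variance = pco$percent_variance),
          "results/pcoa_eigen.csv", row.names = FALSE)
write.csv(data.frame(pop_id = rownames(pco$coordinates), pco$coordinates),
          "results/pcoa_coords.csv", row.names = FALSE)
cat(sprintf("PCoA axes 1 and 2 explain %.2f%% and %.2f%% of the variance\n",
            pco$percent_variance[1], pco$percent_variance[2]))
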