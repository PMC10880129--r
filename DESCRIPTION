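Package: urbanpopgen
Title: Population-Genetic Analysis of Urban and Rural Plant Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end population-genetic analysis of diploid SNP genotypes
    sampled from populations spread across an urban-rural landscape mosaic.
    Provides genotype-matrix input (VCF and a simple CSV dialect), locus and
    sample filtering in the style of the Stacks 'populations' stage,
    per-population diversity statistics (observed and expected
    heterozygosity, rarefied allelic richness, inbreeding coefficient) with
    an exact Hardy-Weinberg test, pairwise Nei genetic distance and
    fixation-index matrices with principal coordinate analysis, geographic
    (haversine) and landscape-composition (Bray-Curtis) distance matrices,
    Mantel and partial Mantel permutation tests plus cross-habitat
    permutation confidence intervals and habitat-pair resampling, Gaussian
    GLM comparisons with AIC-based landscape spatial-scale selection, and a
    forward-time Wright-Fisher simulator with partial selfing,
    habitat-structured migration and founder events so that the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    vegan,
    ape,
    geosphere,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
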