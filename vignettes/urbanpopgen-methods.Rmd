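---
title: "Methods: population-genetic analysis across an urban landscape mosaic"
author: "urbanpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population-genetic analysis across an urban landscape mosaic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model of the data

`urbanpopgen` analyses diploid biallelic SNP genotypes sampled from many
small populations spread over an urban-rural landscape. The data model is
deliberately minimal: a genotype is the dosage of the alternate allele
(0, 1, 2) or missing, individuals map to populations, and populations
carry coordinates (WGS84 decimal degrees) plus land-cover composition
(developed, agricultural, forest, grassland areas) within 250 m, 500 m
and 1 km buffers. Allele identities are never interpreted: every
statistic in the package is invariant to swapping reference and
alternate labels, which is why the containers keep no nucleotide
information.

The organisms this design targets are highly selfing annual plants
(mixed-mating, selfing rate s often above 0.8). Two consequences drive
several choices below: observed heterozygosity is far below
Hardy-Weinberg expectation everywhere (so the Hardy-Weinberg test is a
data-quality and mating-system check, not a surprise generator), and
per-population samples are tiny (3-7 individuals), so every estimator
must behave sensibly at a handful of gene copies.

## Filtering

Filters replicate the genotype-matrix behaviour of the *populations*
stage of a Stacks workflow. Defaults: minor-allele frequency >= 0.01,
observed heterozygosity <= 0.95, locus call rate >= 0.8, all computed
over individuals pooled (single population group), plus exclusion of
individuals with strictly more than 40% missing calls, which runs before
the locus filters (mirroring a design where a failed population is
dropped before any statistics). Published workflows of this kind rarely state an
order for the locus filters; we fix coverage -> single-SNP -> maf ->
heterozygosity, record it in the `FilterReport`, and note that the order
matters only for borderline loci. Comparisons are `>=` (keep) for
coverage and maf, `<=` (keep) for heterozygosity and strictly `>`
(remove) for sample missingness, matching the usual phrasing of each
rule.

## Diversity statistics

* **H_O** is heterozygous calls over called genotypes per population and
  locus; population values are means over defined loci.
* **H_E** defaults to the unbiased gene diversity
  `2n/(2n-1) * (1 - sum p^2)` — the probability that two gene copies
  drawn *without* replacement differ — matching the `basic.stats`
  family of estimators; the plain `1 - sum p^2` is a flag because the
  estimator choice is rarely stated in applied papers.
* **Allelic richness** is hypergeometric rarefaction: the expected
  number of distinct alleles in a subsample of g gene copies. The
  default g = 5 *gene copies* follows the hierfstat convention for "5
  rarefied alleles"; an alternative reading (5 diploid individuals, 10
  copies) exists, so g is a parameter. With 3-7 sampled individuals and
  ~25% missing data, 5 copies is close to the largest size every
  population can support; loci below g copies in a population are
  skipped there rather than imputed.
* **F_IS** is `1 - H_O/H_E`. The multilocus population value aggregates
  as a ratio of sums, `1 - sum(H_O)/sum(H_E)`, not a mean of per-locus
  ratios: near-monomorphic loci make per-locus ratios explode, while the
  ratio-of-sums form is stable and converges on the mating-system
  expectation `F = s/(2-s)` in simulation.
* The **Hardy-Weinberg test** is the exact conditional test for
  biallelic genotypes (probability of each heterozygote count given the
  allele counts, the Levene distribution). The GenoDive-class tools common in this
  literature test the same hypothesis by permutation; for biallelic
  data the exact test is the deterministic equivalent and needs no
  Monte Carlo error budget.
  Probabilities are computed in log space over the support and
  normalised, so large samples do not overflow. One-sided
  heterozygote-deficit and two-sided p-values are both reported;
  monomorphic cells get p = 1 and a flag.

## Differentiation and ordination

Nei's (1972) standard distance `D = -ln(J_AB / sqrt(J_A J_B))` is the
default genetic distance because the commonly used pairwise
implementation (GenAlEx) defaults to the 1972 statistic; loci undefined
in either population are excluded pairwise, and a pair sharing no
alleles yields an `Inf` sentinel that is *excluded* (population dropped
with a warning) from Mantel/PCoA inputs rather than truncated to an
arbitrary cap. F_ST defaults to the Nei/G_ST-style ratio-of-locus-sums
estimator for the same tool-compatibility reason; the Weir-Cockerham
theta is available as a flag and is the better choice when near-zero
true differentiation must not be masked by small-sample bias (the
G_ST-style estimator is biased upward by roughly `1/(2n)` at small
samples — visible in the package's own null-scenario tests).

PCoA delegates Gower double-centering, eigendecomposition and the
Lingoes/Cailliez corrections to `ape::pcoa()`. Axis percentages are
reported relative to the sum of *positive* eigenvalues and the relative
mass of negative eigenvalues is reported separately, because Bray-Curtis
landscape input is semimetric and legitimately produces negative
eigenvalues.

## Spatial and landscape distances

Geographic distances are haversine on a sphere of radius 6371.0088 km;
at a study extent of tens of kilometres the sub-0.5% difference from a
geodesic cannot change rank-based inference. Landscape dissimilarity is
Bray-Curtis over land-cover areas. The default classes are developed,
agricultural and forest: landscape-genetic analyses of this design
typically enter exactly those three classes into the dissimilarity even
where four are tabulated, so grassland is excluded by default and
includable by flag. The default
radius is 500 m; all three radii remain computable because the pipeline
chooses a radius empirically (highest all-pairs Mantel correlation with
the genetic distance), and that choice is kept independent of the
GLM/AIC scale selection for diversity — they answer different questions
and may disagree.

## Resampling inference

Mantel and partial Mantel tests delegate to vegan (joint row/column
permutation; one-sided "greater" p-values by convention, with a
two-sided option). Partial Mantel uses the first-order partial
correlation with permutation of the first matrix. All permutation
machinery takes an explicit integer seed; there is no hidden global
state, and results are reproducible bit-for-bit.

Two procedures are bespoke because no off-the-shelf tool restricts
itself to *between-group* population pairs:

* **Cross-group correlation CI**: the observed statistic is the Pearson
  correlation of genetic vs geographic (or landscape) distance over
  exactly the pairs with one population in each of two habitats. The
  null permutes population labels within the union of the two groups
  (sizes preserved) and recomputes the correlation on the induced
  between-group pairs; the 95% percentile interval of that null is
  reported and the observed value is flagged when it falls outside.
  Published descriptions of this procedure are ambiguous between this
  reading and a bootstrap CI of the observed correlation; intervals
  that straddle zero while some observed r are called significant are
  consistent with the null reading, which is the default — the
  bootstrap is a flag.
* **Habitat-pair resampling**: per replicate, one population pair is
  drawn from each pair category (within-habitat, each habitat pairing,
  and all pairs); category means and 2.5/97.5 percentiles of 1000
  replicates are compared via a CI-overlap matrix. Percentile intervals
  are used, not BCa — the procedure being emulated states only "95%
  CIs".

## GLMs and scale selection

Habitat comparisons and landscape models are Gaussian identity-link GLMs
(ordinary least squares) with treatment coding and the rural
agricultural class as reference. The log-likelihood keeps its
normalising constants and AIC counts the variance parameter
(`AIC = -2 logLik + 2(k+1)`), so values match mainstream software.
Scale selection fits the null model and one model per radius (developed,
agricultural, forest areas, z-scored for conditioning — selection is
invariant to the scaling) and takes the AIC minimum, breaking exact ties
toward fewer predictors.

## The simulator

The forward-time generator exists so the entire pipeline is testable
without any external download. It is a hybrid: migration acts on
population allele frequencies (building the outcrossing gamete pool,
`p_i' = (1 - sum m_ij) p_i + sum m_ij p_j`), while reproduction is
individual-based — each offspring selfs with probability s (gametes from
one random parent) or is formed from two independent Bernoulli(p')
gametes, realising binomial drift at size N. This keeps 600-locus,
24-population runs at a few seconds while preserving the identity
structure (F_IS) that a purely frequency-based simulator would lose.
Migration therefore only enters through outcrossed offspring; under high
selfing the effective migrant influx is reduced by (1-s), which is
biologically the intended behaviour for a selfing annual.

Defaults mirror the emulated study design: 24 populations (8 RA, 5 UA, 5 UP,
6 UR) in a bounding box spanning roughly 66 km, 600 unlinked loci,
s = 0.9, 3-7 sampled individuals per population, ~25% missingness.
Initial frequencies are Beta(0.8, 0.8), a U-shaped spectrum whose common
variants survive a 1% MAF filter. UA coordinates are contracted toward
the regional centre so that the geographic clustering of urban
agricultural remnants — a real confounder of habitat effects — is
reproduced. Missingness is structured: logit-normal per-locus and
per-individual effects (sd 1.5 and 0.6 in the study scenario) around the
target mean, mimicking reduced-representation dropout where some loci
genotype poorly everywhere and some samples fail broadly. This is what
makes the coverage filter behave realistically (most loci either pass
comfortably or fail badly) and occasionally produces a >40%-missing
individual that the sample filter removes, as happens in real data sets
of this kind.

Named scenarios fix the remaining parameters: `ibd` (8 populations on a
line, migration decaying with distance, e-folding 7 km at baseline rate
0.1 — chosen to put neighbouring-pair F_ST near 0.05 and distant pairs
near drift saturation, a regime where isolation by distance is clearly
expressed), `island` (same geometry, uniform migration; the negative
control), `habitat_divergence` (migration additionally decaying with
landscape dissimilarity), `founder_parks` (park and roadside populations
founded by 5 individuals from the nearest agricultural source 15
generations before sampling), and `null` (12 populations, strong island
migration, moderate selfing; effectively panmictic).

What the generator does *not* emulate: linkage (loci are exchangeable
and unlinked, as appropriate for one-SNP-per-locus data), mutation, seed
banks, selection, polyploidy, and genotyping error other than dropout.
Tests passing on these simulations therefore demonstrate that the
statistics recover the structure the model contains — mating system,
drift, structured migration, founder events — not that any particular
field data set is free of the unmodelled complications.

## Numerical and testing choices

Rarefaction uses `choose()` directly (exact at the <= 14 gene copies per
population-locus cell this design produces). The exact HWE distribution
is validated against Levene's closed form; rarefaction against
exhaustive subsample enumeration (all copy counts up to 12); Mantel
p-values against complete enumeration of all 24 relabelings of 4x4
matrices; PCoA against known planar configurations (Procrustes RMS below
1e-6) and `cmdscale`. Calibration checks run 200 replicates of
independent random 11x11 matrices at 199 permutations (Mantel and the
cross-group procedure both hold 5% nominal size within [0.02, 0.10] and
[0.01, 0.11]); power checks use 20 replicates of the `ibd`/`island`
scenarios and 10 of `founder_parks`; the F_IS equilibrium check uses 10
runs of a single population at s = 0.9, N = 200, 500 loci, 50
generations. These problem sizes keep the whole suite at about a minute
while leaving the binomial success bounds comfortably away from their
thresholds.

## Known limitations

Only biallelic diploid data are supported; the emulated species may be
polyploid, and read-depth-based genotype uncertainty is not modelled.
The G_ST-style F_ST retains small-sample bias (use the Weir-Cockerham
flag when absolute values matter). The cross-group CI procedure, like
the design it reproduces, conditions on the observed group sizes and is
sensitive to very small groups (it refuses below 3 between-group
pairs). Mantel-family tests have well-known limitations under spatial
autocorrelation; they are used here because the analysis being
reproduced is defined in terms of them.
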