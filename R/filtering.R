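#' Filter configuration for the genotype-matrix filters
#'
#' Mirrors the genotype-matrix-level behaviour of the Stacks `populations`
#' stage: a locus is retained iff its called-genotype fraction across all
#' individuals is at least `min_locus_coverage`, its global minor-allele
#' frequency over called gene copies is at least `min_maf`, and its global
#' observed heterozygosity is at most `max_obs_het`; optionally only the
#' first SNP per locus group is kept. Individuals whose missing-call
#' fraction exceeds `max_sample_missing` (strictly) are excluded before the
#' locus filters run.
#'
#' @param min_maf minimum global minor-allele frequency, in `[0, 0.5]`.
#' @param max_obs_het maximum global observed heterozygosity, in `[0, 1]`.
#' @param min_locus_coverage minimum called fraction per locus (`r` in
#'   Stacks), in `[0, 1]`.
#' @param max_sample_missing individuals with missingness strictly above
#'   this are dropped.
#' @param single_snp keep only the first SNP of each locus group, when
#'   groups are supplied.
#' @return a list of class `filter_config`.
#' @export
filter_config <- function(min_maf = 0.01, max_obs_het = 0.95,
                          min_locus_coverage = 0.8,
                          max_sample_missing = 0.40, single_snp = TRUE) {
  stopifnot(min_maf >= 0, min_maf <= 0.5,
            max_obs_het >= 0, max_obs_het <= 1,
            min_locus_coverage >= 0, min_locus_coverage <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1,
            is.logical(single_snp))
  structure(list(min_maf = min_maf, max_obs_het = max_obs_het,
                 min_locus_coverage = min_locus_coverage,
                 max_sample_missing = max_sample_missing,
                 single_snp = single_snp),
            class = "filter_config")
}

#' Drop individuals with excessive missing data
#'
#' An individual is removed iff its missing-call fraction is strictly
#' greater than `max_sample_missing` (a sample at exactly the threshold is
#' retained).
#'
#' @param g a [genotype_matrix()].
#' @param max_sample_missing proportion in `[0, 1]`.
#' @return list with elements `genotypes` (filtered matrix) and `report`.
#' @export
drop_high_missing_samples <- function(g, max_sample_missing = 0.40) {
  miss <- sample_missingness(g)
  drop <- miss > max_sample_missing
  if (all(drop))
    stop("all ", length(drop), " samples exceed missingness threshold ",
         max_sample_missing)
  out <- if (any(drop)) subset_genotypes(g, individuals = names(miss)[!drop]) else g
  report <- list(stage = "sample_missingness",
                 threshold = max_sample_missing,
                 n_in = length(miss), n_removed = sum(drop),
                 removed = names(miss)[drop], retained = names(miss)[!drop])
  list(genotypes = out, report = report)
}

# global per-locus summaries over all individuals pooled
locus_summaries <- function(g) {
  called <- colSums(!is.na(g$geno))
  alt <- colSums(g$geno, na.rm = TRUE)
  het <- colSums(g$geno == 1L, na.rm = TRUE)
  p_alt <- ifelse(called > 0, alt / (2 * called), NA_real_)
  list(coverage = called / nrow(g$geno),
       maf = pmin(p_alt, 1 - p_alt),
       h_obs = ifelse(called > 0, het / called, NA_real_))
}

#' Apply the locus-level filters
#'
#' Filters are applied in the order coverage -> single-SNP -> maf -> het;
#' the order matters for borderline loci and is recorded in the report.
#' maf and observed heterozygosity are computed over all individuals pooled
#' (global filtering, one population group).
#'
#' @param g a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @param locus_groups optional named vector mapping locus id to a locus
#'   group (e.g. the RAD locus a SNP came from); used by the single-SNP rule.
#' @return list with elements `genotypes` and `report`; the report lists,
#'   per filter in application order, the loci it removed.
#' @export
apply_locus_filters <- function(g, cfg = filter_config(), locus_groups = NULL) {
  stopifnot(inherits(cfg, "filter_config"))
  keep <- locus_ids(g)
  steps <- list()

  s <- locus_summaries(subset_genotypes(g, loci = keep))
  fail <- keep[is.na(s$coverage) | s$coverage < cfg$min_locus_coverage]
  steps$coverage <- fail
  keep <- setdiff(keep, fail)

  if (cfg$single_snp && !is.null(locus_groups)) {
    grp <- locus_groups[keep]
    fail <- keep[duplicated(grp) & !is.na(grp)]
  } else fail <- character(0)
  steps$single_snp <- fail
  keep <- setdiff(keep, fail)

  if (length(keep)) {
    s <- locus_summaries(subset_genotypes(g, loci = keep))
    fail <- keep[s$maf < cfg$min_maf]
  } else fail <- character(0)
  steps$maf <- fail
  keep <- setdiff(keep, fail)

  if (length(keep)) {
    s <- locus_summaries(subset_genotypes(g, loci = keep))
    fail <- keep[s$h_obs > cfg$max_obs_het]
  } else fail <- character(0)
  steps$het <- fail
  keep <- setdiff(keep, fail)

  if (!length(keep))
    stop("no loci retained by the filters")
  report <- list(stage = "locus_filters", config = unclass(cfg),
                 order = c("coverage", "single_snp", "maf", "het"),
                 n_in = ncol(g$geno),
                 n_removed = vapply(steps, length, integer(1)),
                 removed = steps, retained = keep)
  list(genotypes = subset_genotypes(g, loci = keep), report = report)
}

#' Run the full filter chain
#'
#' Sample exclusion runs first (matching the study design, where one
#' population was dropped for missingness before any statistics), then the
#' locus filters.
#'
#' @inheritParams apply_locus_filters
#' @return list with `genotypes` and a combined `report` (JSON-serialisable).
#' @export
filter_genotypes <- function(g, cfg = filter_config(), locus_groups = NULL) {
  a <- drop_high_missing_samples(g, cfg$max_sample_missing)
  b <- apply_locus_filters(a$genotypes, cfg, locus_groups)
  list(genotypes = b$genotypes,
       report = list(samples = a$report, loci = b$report))
}

#' Serialise a filter report as JSON
#'
#' @param report the `report` element from [filter_genotypes()].
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
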