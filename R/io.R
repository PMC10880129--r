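#' Read genotypes from a VCF file
#'
#' Only the GT field is used. Records must be biallelic; multiallelic records
#' either abort the read or are dropped, depending on `multiallelic`. Phased
#' (`|`) and unphased (`/`) separators are treated identically, `./.` is
#' missing, and half-called genotypes (e.g. `./1`) are set to missing with a
#' message.
#'
#' @param path path to a VCF (optionally bgzipped).
#' @param pop_of named character vector mapping sample id to population id,
#'   or a metadata data frame from [read_metadata()] together with a
#'   `sample_pops` mapping is not needed if sample names are `<pop>_<k>`.
#'   Every VCF sample must be present in the mapping.
#' @param multiallelic `"error"` (default) to refuse records with more than
#'   one ALT allele, `"drop"` to discard them with a message.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, pop_of, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  vcf <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                  error = function(e) stop("malformed VCF '", path, "': ",
                                           conditionMessage(e)))
  alt <- vcf@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    if (multiallelic == "error")
      stop("multiallelic record(s) at VCF data line(s) ",
           paste(which(multi), collapse = ", "),
           " (ALT lists several alleles); rerun with multiallelic = \"drop\"")
    vcf <- vcf[!multi, ]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt) || !nrow(gt)) stop("VCF '", path, "' has no GT genotypes")
  ids <- unname(as.character(vcf@fix[, "ID"]))
  anon <- is.na(ids) | ids == "."
  ids[anon] <- paste0(vcf@fix[anon, "CHROM"], "_", vcf@fix[anon, "POS"])
  rownames(gt) <- ids
  geno <- parse_gt_strings(gsub("|", "/", gt, fixed = TRUE))
  geno <- t(geno)  # individuals x loci
  absent <- setdiff(rownames(geno), names(pop_of))
  if (length(absent))
    stop("VCF samples absent from metadata: ", paste(absent, collapse = ", "))
  genotype_matrix(geno, pop_of)
}

# "a/b" strings -> alt dosage; half calls become NA with a message
parse_gt_strings <- function(gt) {
  out <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  out[gt %in% c("0/0")] <- 0L
  out[gt %in% c("0/1", "1/0")] <- 1L
  out[gt %in% c("1/1")] <- 2L
  half <- !is.na(gt) & gt != "./." & grepl(".", gt, fixed = TRUE)
  if (any(half))
    message(sum(half), " half-called genotype(s) treated as missing")
  known <- is.na(gt) | gt %in% c("0/0", "0/1", "1/0", "1/1", "./.") | half
  if (!all(known))
    stop("unknown genotype code(s): ",
         paste(utils::head(unique(gt[!known]), 5), collapse = ", "))
  out
}

#' Write genotypes as a minimal VCF
#'
#' Emits a VCF 4.2 file carrying only the GT field, with placeholder REF/ALT
#' alleles (`A`/`T`) since the container keeps no nucleotide information.
#'
#' @param g a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(g, path) {
  codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(g$geno), ncol = nrow(g$geno))
  called <- !is.na(t(g$geno))
  gt[called] <- codes[t(g$geno)[called] + 1L]
  header <- c("##fileformat=VCFv4.2",
              "##source=urbanpopgen",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", individual_ids(g)), collapse = "\t"))
  body <- paste("sim", seq_len(ncol(g$geno)), locus_ids(g), "A", "T", ".",
                "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read genotypes from the package CSV dialect
#'
#' Rows are individuals. The first two columns are `individual_id` and
#' `pop_id`; every remaining column is one locus with cells `"a/b"`,
#' `a, b` in `{0, 1}` (order irrelevant), or `"NA"` for missing. The dialect
#' is fixed: comma-separated, UTF-8, header row required.
#'
#' @param path path to the CSV file.
#' @return a [genotype_matrix()].
#' @export
read_genotype_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = "NA")
  if (ncol(df) < 3 || !identical(names(df)[1:2], c("individual_id", "pop_id")))
    stop("genotype CSV must start with columns individual_id, pop_id")
  if (anyDuplicated(df$individual_id))
    stop("duplicate individual_id in ", path)
  gt <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(gt) <- df$individual_id
  geno <- parse_gt_strings(gt)
  pop_of <- stats::setNames(df$pop_id, df$individual_id)
  genotype_matrix(geno, pop_of)
}

#' @rdname read_genotype_csv
#' @param g a [genotype_matrix()].
#' @export
write_genotype_csv <- function(g, path) {
  codes <- c("0/0", "0/1", "1/1")
  cells <- matrix(NA_character_, nrow(g$geno), ncol(g$geno),
                  dimnames = dimnames(g$geno))
  called <- !is.na(g$geno)
  cells[called] <- codes[g$geno[called] + 1L]
  df <- data.frame(individual_id = individual_ids(g),
                   pop_id = unname(g$pops), cells, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read population metadata
#'
#' Expects columns `pop_id`, `habitat`, `lat`, `lon`, then land-cover area
#' columns named `<class>_<radius>` with class in developed / agricultural /
#' forest / grassland and radius in 250, 500, 1000 (metres); areas in square
#' metres. A radius may be absent entirely, but if any class column is
#' present for a radius all four must be.
#'
#' @param path CSV path.
#' @return a validated data frame of class `pop_meta`, one row per population.
#' @export
read_metadata <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  validate_metadata(df)
}

#' @rdname read_metadata
#' @param df a data frame with the columns described above.
#' @export
validate_metadata <- function(df) {
  need <- c("pop_id", "habitat", "lat", "lon")
  if (!all(need %in% names(df)))
    stop("metadata must contain columns ", paste(need, collapse = ", "))
  if (anyDuplicated(df$pop_id)) stop("duplicate pop_id in metadata")
  bad_hab <- setdiff(unique(df$habitat), habitat_levels())
  if (length(bad_hab))
    stop("unknown habitat code(s): ", paste(bad_hab, collapse = ", "),
         " (expected RA, UA, UP, UR)")
  if (any(df$lat < -90 | df$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(df$lon < -180 | df$lon > 180)) stop("longitude outside [-180, 180]")
  for (r in landcover_radii()) {
    cols <- paste0(landcover_classes(), "_", r)
    present <- cols %in% names(df)
    if (any(present) && !all(present))
      stop("radius ", r, " m has columns ",
           paste(cols[present], collapse = ", "), " but is missing ",
           paste(cols[!present], collapse = ", "))
    if (all(present) && any(as.matrix(df[, cols]) < 0, na.rm = TRUE))
      stop("negative land-cover area at radius ", r)
  }
  class(df) <- c("pop_meta", "data.frame")
  df
}

habitat_levels <- function() c("RA", "UA", "UP", "UR")
landcover_classes <- function() c("developed", "agricultural", "forest", "grassland")
landcover_radii <- function() c(250L, 500L, 1000L)

#' @rdname read_metadata
#' @export
write_metadata <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Radii for which a metadata table carries complete land cover
#'
#' @param meta a `pop_meta` data frame.
#' @return integer vector, subset of `c(250, 500, 1000)`.
#' @export
available_radii <- function(meta) {
  Filter(function(r) all(paste0(landcover_classes(), "_", r) %in% names(meta)),
         landcover_radii())
}

#' Read / write a labelled square distance matrix as TSV
#'
#' @param d a `dist_matrix` (see [distance_matrix()]).
#' @param path file path.
#' @return the matrix (read) or `path` invisibly (write).
#' @export
write_dist_tsv <- function(d, path) {
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname write_dist_tsv
#' @export
read_dist_tsv <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   row.names = 1, check.names = FALSE))
  dist_matrix_obj(m)
}

# internal constructor/validator for labelled symmetric matrices
dist_matrix_obj <- function(m, kind = "generic") {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8, check.attributes = FALSE)))
    stop("distance matrix is not symmetric")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  attr(m, "kind") <- kind
  class(m) <- c("dist_matrix", class(m))
  m
}
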