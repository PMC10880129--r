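#' Default pipeline configuration
#'
#' @param input either `list(scenario = <name>, seed = <int>)` to simulate,
#'   or `list(genotypes = <path>, format = "csv"|"vcf", metadata = <path>)`
#'   to analyse files on disk.
#' @param filters a [filter_config()].
#' @param g_copies rarefaction size for allelic richness.
#' @param unbiased_he use the unbiased expected-heterozygosity estimator.
#' @param n_perm Mantel / cross-group permutations.
#' @param n_reps habitat-pair resampling replicates.
#' @param seed master seed for all inference stages.
#' @return config list.
#' @export
pipeline_config <- function(input = list(scenario = "study", seed = 1L),
                            filters = filter_config(),
                            g_copies = 5, unbiased_he = TRUE,
                            n_perm = 999, n_reps = 1000, seed = 1L) {
  list(input = input, filters = filters, g_copies = g_copies,
       unbiased_he = unbiased_he, n_perm = n_perm, n_reps = n_reps,
       seed = seed)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the [pipeline_config()] fields;
#'   `filters` entries are passed to [filter_config()].
#' @return config list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  if (!is.null(y$filters)) cfg$filters <- do.call(filter_config, y$filters)
  for (f in setdiff(names(y), "filters")) cfg[[f]] <- y[[f]]
  cfg
}

# drop labels carrying non-finite entries until the matrix is finite
finite_submatrix <- function(d) {
  while (any(!is.finite(d))) {
    worst <- which.max(rowSums(!is.finite(d)))
    warning("dropping population ", rownames(d)[worst],
            " (non-finite distances) from ordination/Mantel input")
    keep <- setdiff(seq_len(nrow(d)), worst)
    d <- d[keep, keep, drop = FALSE]
  }
  d
}

sub_dist <- function(d, pops) d[pops, pops, drop = FALSE]

#' Run the full analysis pipeline
#'
#' Executes, in order: input (simulation or file read) -> sample and locus
#' filtering -> per-population diversity and exact Hardy-Weinberg tests ->
#' Nei and F_ST distance matrices and their Mantel concordance -> PCoA ->
#' geographic and landscape distance matrices -> within-habitat Mantel
#' (genetic vs geographic) and partial Mantel (genetic vs landscape given
#' geography) -> cross-habitat correlation CIs for all six habitat
#' pairings (geographic and landscape) -> landscape Mantel at the three
#' buffer radii with the best radius chosen by Mantel r -> habitat-pair
#' resampling CIs -> habitat GLMs and AIC landscape-scale selection.
#' Every table is written into `out_dir` along with a manifest (inputs,
#' seed, versions) that suffices to reproduce the run.
#'
#' @param config a [pipeline_config()] (or path to a YAML file).
#' @param out_dir output directory (created; default a tempdir subdir).
#' @return invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         out_dir = tempfile("run_")) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- input ------------------------------------------------------------
  inp <- config$input
  manifest_input <- inp
  res <- stage("input", {
    if (!is.null(inp$scenario)) {
      scn <- do.call(scenario_library,
                     c(list(inp$scenario,
                            seed = if (is.null(inp$seed)) 1L else inp$seed),
                       inp$overrides))
      simulate_scenario(scn)
    } else {
      g <- if (identical(inp$format, "vcf")) {
        meta0 <- read_metadata(inp$metadata)
        stop("VCF input needs a sample->population mapping; use read_vcf() ",
             "directly or the CSV dialect")
      } else read_genotype_csv(inp$genotypes)
      list(genotypes = g, meta = read_metadata(inp$metadata), truth = NULL)
    }
  })
  g_raw <- res$genotypes
  meta <- res$meta
  logf("input: %d individuals x %d loci, %d populations",
       nrow(g_raw$geno), ncol(g_raw$geno), length(population_ids(g_raw)))

  # --- filtering --------------------------------------------------------
  filt <- stage("filtering", filter_genotypes(g_raw, config$filters))
  g <- filt$genotypes
  write_filter_report(filt$report, file.path(out_dir, "filter_report.json"))
  logf("filtering: %d/%d loci and %d/%d samples retained",
       ncol(g$geno), ncol(g_raw$geno), nrow(g$geno), nrow(g_raw$geno))
  meta <- meta[meta$pop_id %in% population_ids(g), , drop = FALSE]
  landscape_ok <- length(available_radii(meta)) == 3

  # --- diversity + HWE --------------------------------------------------
  freqs <- stage("diversity", allele_frequencies(g))
  div <- stage("diversity", diversity_table(g, g_copies = config$g_copies,
                                            unbiased_he = config$unbiased_he))
  hwe <- stage("hwe", hwe_exact_test(freqs))
  utils::write.csv(div, file.path(out_dir, "diversity.csv"), row.names = FALSE)
  utils::write.csv(hwe$per_population, file.path(out_dir, "hwe.csv"),
                   row.names = FALSE)
  coverage <- mean(!is.na(g$geno))

  # --- genetic distances + concordance + PCoA ---------------------------
  d_nei <- stage("distances", distance_matrix(freqs, "nei"))
  d_fst <- stage("distances", distance_matrix(freqs, "fst"))
  write_dist_tsv(d_nei, file.path(out_dir, "dist_nei.tsv"))
  write_dist_tsv(d_fst, file.path(out_dir, "dist_fst.tsv"))
  nei_f <- finite_submatrix(d_nei)
  concord <- stage("mantel", mantel_test(nei_f,
                                         sub_dist(d_fst, rownames(nei_f)),
                                         n_perm = config$n_perm,
                                         seed = config$seed))
  pco <- stage("pcoa", pcoa_ordination(nei_f))
  utils::write.csv(data.frame(axis = seq_along(pco$percent_variance),
                              eigenvalue = pco$eigenvalues[
                                seq_along(pco$percent_variance)],
                              percent_variance = pco$percent_variance),
                   file.path(out_dir, "pcoa_eigen.csv"), row.names = FALSE)
  utils::write.csv(data.frame(pop_id = rownames(pco$coordinates),
                              pco$coordinates, check.names = FALSE),
                   file.path(out_dir, "pcoa_coords.csv"), row.names = FALSE)

  # --- spatial / landscape matrices -------------------------------------
  d_geo <- stage("spatial", geographic_distance(meta))
  write_dist_tsv(d_geo, file.path(out_dir, "dist_geo.tsv"))
  d_land <- NULL
  if (landscape_ok) {
    d_land <- lapply(stats::setNames(nm = landcover_radii()), function(r)
      landscape_distance(meta, radius = r))
    for (r in names(d_land))
      write_dist_tsv(d_land[[r]], file.path(out_dir,
                                            paste0("dist_landscape_", r, ".tsv")))
  } else {
    warning("land-cover table incomplete; landscape stages skipped")
    logf("landscape stages skipped: incomplete land cover")
  }

  habitats <- stats::setNames(meta$habitat, meta$pop_id)
  mantel_rows <- list()
  add_row <- function(test, r, p, lo = NA, hi = NA) {
    mantel_rows[[length(mantel_rows) + 1]] <<-
      data.frame(test = test, r = r, p = p, ci_low = lo, ci_high = hi)
  }
  add_row("nei_vs_fst", concord$observed, concord$p)

  # --- landscape scale choice by Mantel r (all pairs) -------------------
  best_radius <- NA_integer_
  if (landscape_ok) {
    r_by_radius <- vapply(names(d_land), function(r) {
      m <- stage("mantel", mantel_test(nei_f,
                                       sub_dist(d_land[[r]], rownames(nei_f)),
                                       n_perm = config$n_perm,
                                       seed = config$seed))
      add_row(paste0("nei_vs_landscape_", r), m$observed, m$p)
      m$observed
    }, numeric(1))
    best_radius <- as.integer(names(which.max(r_by_radius)))
    logf("landscape radius chosen by Mantel r: %d m", best_radius)
  }

  # --- within-habitat tests ---------------------------------------------
  for (h in intersect(habitat_levels(), unique(habitats))) {
    pops <- intersect(names(habitats)[habitats == h], rownames(nei_f))
    if (length(pops) < 4) {
      logf("within-%s tests skipped (%d populations)", h, length(pops))
      next
    }
    gsub_ <- sub_dist(nei_f, pops)
    m <- stage("mantel", mantel_test(gsub_, sub_dist(d_geo, pops),
                                     n_perm = config$n_perm,
                                     seed = config$seed))
    add_row(paste0("within_", h, "_geo"), m$observed, m$p)
    if (landscape_ok) {
      pm <- stage("mantel",
                  partial_mantel_test(gsub_,
                                      sub_dist(d_land[[as.character(best_radius)]],
                                               pops),
                                      sub_dist(d_geo, pops),
                                      n_perm = config$n_perm,
                                      seed = config$seed))
      add_row(paste0("within_", h, "_landscape_given_geo"), pm$observed, pm$p)
    }
  }

  # --- cross-habitat correlation CIs ------------------------------------
  pairings <- list(c("RA", "UA"), c("RA", "UP"), c("RA", "UR"),
                   c("UA", "UP"), c("UA", "UR"), c("UP", "UR"))
  cross_rows <- list()
  for (pr in pairings) {
    hab_sub <- habitats[names(habitats) %in% rownames(nei_f)]
    if (sum(hab_sub == pr[1]) < 2 || sum(hab_sub == pr[2]) < 2) next
    for (kind in c("geo", if (landscape_ok) "landscape")) {
      ymat <- if (kind == "geo") d_geo else d_land[[as.character(best_radius)]]
      cg <- stage("crossgroup",
                  cross_group_correlation_ci(nei_f,
                                             sub_dist(ymat, rownames(nei_f)),
                                             hab_sub, pr[1], pr[2],
                                             n_perm = config$n_reps,
                                             seed = config$seed))
      cross_rows[[length(cross_rows) + 1]] <- data.frame(
        pairing = paste0(pr[1], "_", pr[2]), distance = kind,
        r = cg$observed, ci_low = cg$ci_low, ci_high = cg$ci_high,
        significant = cg$significant, n_pairs = cg$n_pairs)
    }
  }
  crossgroup <- do.call(rbind, cross_rows)
  utils::write.csv(crossgroup, file.path(out_dir, "crossgroup.csv"),
                   row.names = FALSE)

  # --- habitat-pair resampling ------------------------------------------
  sets <- stage("pairci", build_pair_sets(
    habitats[names(habitats) %in% rownames(nei_f)]))
  pairci <- stage("pairci", habitat_pair_resample(nei_f, sets,
                                                  n_reps = config$n_reps,
                                                  seed = config$seed))
  utils::write.csv(pairci$summary, file.path(out_dir, "pairci.csv"),
                   row.names = FALSE)

  # --- GLMs --------------------------------------------------------------
  metric_cols <- c("N_A", "A_R", "H_O", "H_E", "F_IS")
  glm_rows <- lapply(metric_cols, function(mc) {
    fit <- stage("glm", habitat_glm(div, meta, mc))
    cf <- fit$coefficients
    cbind(metric = mc, cf, aic = fit$aic)
  })
  glm_habitat <- do.call(rbind, glm_rows)
  utils::write.csv(glm_habitat, file.path(out_dir, "glm_habitat.csv"),
                   row.names = FALSE)
  glm_scale <- NULL
  if (landscape_ok) {
    glm_scale <- stage("glm", select_landscape_scale(div, meta))
    utils::write.csv(glm_scale, file.path(out_dir, "glm_scale.csv"),
                     row.names = FALSE)
  }

  mantel_df <- do.call(rbind, mantel_rows)
  utils::write.csv(mantel_df, file.path(out_dir, "mantel_tests.csv"),
                   row.names = FALSE)

  # --- manifest ----------------------------------------------------------
  file_inputs <- unlist(Filter(is.character, manifest_input))
  hashes <- if (length(file_inputs) && all(file.exists(file_inputs)))
    as.list(tools::md5sum(file_inputs)) else NULL
  manifest <- list(
    package = "urbanpopgen",
    version = as.character(utils::packageVersion("urbanpopgen")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = manifest_input, input_md5 = hashes,
    filters = unclass(config$filters),
    g_copies = config$g_copies, unbiased_he = config$unbiased_he,
    n_perm = config$n_perm, n_reps = config$n_reps, seed = config$seed,
    best_landscape_radius_m = best_radius,
    coverage_rate = coverage)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(out_dir = out_dir, genotypes = g, meta = meta,
                 filter_report = filt$report, diversity = div, hwe = hwe,
                 freqs = freqs, dist_nei = d_nei, dist_fst = d_fst,
                 dist_geo = d_geo, dist_landscape = d_land,
                 nei_vs_fst = concord, pcoa = pco, mantel = mantel_df,
                 crossgroup = crossgroup, pairci = pairci,
                 glm_habitat = glm_habitat, glm_scale = glm_scale,
                 best_landscape_radius = best_radius,
                 coverage_rate = coverage, truth = res$truth,
                 manifest = manifest))
}

#' Summarise a completed pipeline run
#'
#' Regenerates (idempotently) a plain-markdown summary of a run directory:
#' diversity per population, Hardy-Weinberg deviation, the Mantel grid,
#' cross-habitat CIs, the habitat-pair CI comparison and PCoA variance.
#'
#' @param run_dir directory written by [run_pipeline()].
#' @return path of the report, invisibly.
#' @export
report_run <- function(run_dir) {
  need <- c("manifest.json", "diversity.csv", "mantel_tests.csv",
            "pcoa_eigen.csv", "pairci.csv")
  miss <- need[!file.exists(file.path(run_dir, need))]
  if (length(miss))
    stop("incomplete run: missing ", paste(miss, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  rd <- function(f) utils::read.csv(file.path(run_dir, f))
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], round, 4)
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  lines <- c("# Pipeline run summary", "",
             sprintf("Seed %s, %s permutations, coverage rate %.3f.",
                     manifest$seed, manifest$n_perm,
                     manifest$coverage_rate), "",
             "## Diversity per population", "", fmt(rd("diversity.csv")), "",
             "## Hardy-Weinberg deviation", "", fmt(rd("hwe.csv")), "",
             "## Mantel tests", "", fmt(rd("mantel_tests.csv")), "")
  if (file.exists(file.path(run_dir, "crossgroup.csv")))
    lines <- c(lines, "## Cross-habitat correlation CIs", "",
               fmt(rd("crossgroup.csv")), "")
  lines <- c(lines, "## Habitat-pair resampling CIs", "",
             fmt(rd("pairci.csv")), "",
             "## PCoA variance", "", fmt(rd("pcoa_eigen.csv")), "")
  if (file.exists(file.path(run_dir, "glm_scale.csv")))
    lines <- c(lines, "## GLM landscape-scale selection", "",
               fmt(rd("glm_scale.csv")), "")
  out <- file.path(run_dir, "report.md")
  writeLines(lines, out)
  invisible(out)
}
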