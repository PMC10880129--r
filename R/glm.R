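#' Gaussian identity-link GLM fit
#'
#' A Gaussian GLM with identity link is ordinary least squares; this
#' wrapper fits via [stats::glm()] and extracts the quantities used by the
#' habitat comparisons and AIC model selection. The log-likelihood keeps
#' its normalizing constants and the AIC counts the residual variance as an
#' estimated parameter (`AIC = -2 logLik + 2 (k + 1)` with `k` mean
#' parameters), matching mainstream statistical software.
#'
#' @param formula model formula.
#' @param data data frame.
#' @return list of class `glm_fit`: `coefficients` (estimate, std.error,
#'   t, p per term), `rss`, `n`, `k`, `logLik`, `aic`, and the underlying
#'   `fit` object.
#' @export
fit_gaussian_glm <- function(formula, data) {
  fit <- stats::glm(formula, data = data,
                    family = stats::gaussian(link = "identity"))
  if (fit$rank < length(stats::coef(fit)))
    stop("design matrix is rank deficient")
  n <- stats::nobs(fit)
  k <- fit$rank
  if (n <= k) stop("need more observations than mean parameters")
  cf <- summary.glm_wald(fit)
  structure(list(coefficients = cf,
                 rss = sum(stats::residuals(fit)^2),
                 n = n, k = k,
                 logLik = as.numeric(stats::logLik(fit)),
                 aic = stats::AIC(fit),
                 fit = fit),
            class = "glm_fit")
}

# coefficient table with Wald t tests against 0
summary.glm_wald <- function(fit) {
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
             statistic = s[, 3], p.value = s[, 4], row.names = NULL)
}

#' @export
print.glm_fit <- function(x, ...) {
  cat(sprintf("Gaussian GLM: n = %d, k = %d, AIC = %.2f\n", x$n, x$k, x$aic))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' Compare a diversity metric among habitat types
#'
#' Fits `metric ~ habitat` with treatment coding and RA (rural
#' agricultural) as the reference level, so the habitat coefficients are
#' urban-vs-rural contrasts.
#'
#' @param metrics a [diversity_table()] data frame.
#' @param meta a `pop_meta` data frame.
#' @param metric column of `metrics` to model (e.g. `"H_E"`).
#' @return a `glm_fit`.
#' @export
habitat_glm <- function(metrics, meta, metric) {
  if (!metric %in% names(metrics)) stop("unknown metric: ", metric)
  df <- merge(metrics[, c("pop_id", metric)], meta[, c("pop_id", "habitat")],
              by = "pop_id")
  df$habitat <- factor(df$habitat,
                       levels = intersect(habitat_levels(), df$habitat))
  names(df)[2] <- "y"
  fit_gaussian_glm(y ~ habitat, df)
}

#' AIC selection of the landscape spatial scale for diversity metrics
#'
#' For each diversity metric, fits an intercept-only null model and one
#' model per buffer radius with the developed, agricultural and forest
#' areas at that radius as predictors (z-scored for conditioning; the AIC
#' ranking is invariant to this). The model with the lowest AIC wins; ties
#' are broken toward fewer predictors (the null), and a tie is recorded.
#'
#' @param metrics a [diversity_table()] data frame.
#' @param meta a `pop_meta` data frame carrying land cover at all three
#'   radii (250, 500, 1000 m).
#' @param metric_cols metric columns to analyse.
#' @param classes land-cover classes used as predictors.
#' @return data frame with one row per metric: AIC of null / 250 / 500 /
#'   1000 and the winning scale (`"null"`, `"250"`, `"500"`, `"1000"`).
#' @export
select_landscape_scale <- function(metrics, meta,
                                   metric_cols = c("N_A", "A_R", "H_O",
                                                   "H_E", "F_IS"),
                                   classes = c("developed", "agricultural",
                                               "forest")) {
  radii <- landcover_radii()
  missing_r <- setdiff(radii, available_radii(meta))
  if (length(missing_r))
    stop("metadata lacks complete land cover at radius ",
         paste(missing_r, collapse = ", "))
  df <- merge(metrics, meta, by = "pop_id")
  out <- lapply(metric_cols, function(mc) {
    if (!mc %in% names(metrics)) stop("unknown metric: ", mc)
    y <- df[[mc]]
    aics <- c(null = fit_gaussian_glm(y ~ 1, data.frame(y = y))$aic)
    for (r in radii) {
      X <- scale(as.matrix(df[, paste0(classes, "_", r)]))
      d <- data.frame(y = y, X)
      names(d) <- c("y", classes)
      f <- stats::as.formula(paste("y ~", paste(classes, collapse = " + ")))
      aics[as.character(r)] <- fit_gaussian_glm(f, d)$aic
    }
    # lowest AIC wins; exact ties resolved toward fewer predictors, i.e.
    # the null first, then smaller radius
    winner <- names(aics)[which.min(aics)]
    tied <- abs(aics - min(aics)) < 1e-9
    if (sum(tied) > 1) winner <- names(aics)[which(tied)[1]]
    data.frame(metric = mc, aic_null = aics["null"],
               aic_250 = aics["250"], aic_500 = aics["500"],
               aic_1000 = aics["1000"], best = winner,
               null_best = winner == "null", tie = sum(tied) > 1,
               row.names = NULL)
  })
  do.call(rbind, out)
}
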