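#' Great-circle distance matrix between population sites
#'
#' Haversine distances on a sphere of radius 6371.0088 km (IUGG mean Earth
#' radius). At the spatial extent of an urban study region (tens of km) the
#' sub-0.5% difference from a full geodesic is immaterial to rank-based
#' inference.
#'
#' @param meta a `pop_meta` data frame ([read_metadata()]).
#' @return a `dist_matrix` in kilometres.
#' @export
geographic_distance <- function(meta) {
  if (any(is.na(meta$lat) | is.na(meta$lon)))
    stop("missing coordinates for: ",
         paste(meta$pop_id[is.na(meta$lat) | is.na(meta$lon)], collapse = ", "))
  xy <- cbind(meta$lon, meta$lat)
  n <- nrow(xy)
  m <- matrix(0, n, n, dimnames = list(meta$pop_id, meta$pop_id))
  for (i in seq_len(n)[-1]) for (j in seq_len(i - 1)) {
    m[i, j] <- m[j, i] <-
      geosphere::distHaversine(xy[i, ], xy[j, ], r = 6371008.8) / 1000
  }
  dist_matrix_obj(m, kind = "geographic_km")
}

#' Bray-Curtis landscape-composition distance matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over the selected land-cover
#' classes at the selected buffer radius. The default classes are developed,
#' agricultural and forest (grassland excluded), and the default radius is
#' 500 m, the scale adopted for the downstream analyses.
#'
#' @param meta a `pop_meta` data frame with land-cover columns for `radius`.
#' @param radius buffer radius in metres: 250, 500 or 1000.
#' @param classes subset of developed / agricultural / forest / grassland.
#' @return a `dist_matrix` with entries in `[0, 1]`; attributes `radius`
#'   and `classes` record the selection.
#' @export
landscape_distance <- function(meta, radius = 500,
                               classes = c("developed", "agricultural",
                                           "forest")) {
  radius <- as.integer(radius)
  if (!radius %in% landcover_radii())
    stop("radius must be one of ", paste(landcover_radii(), collapse = ", "))
  classes <- match.arg(classes, landcover_classes(), several.ok = TRUE)
  cols <- paste0(classes, "_", radius)
  missing_cols <- setdiff(cols, names(meta))
  if (length(missing_cols))
    stop("metadata lacks land-cover columns: ",
         paste(missing_cols, collapse = ", "))
  x <- as.matrix(meta[, cols, drop = FALSE])
  rownames(x) <- meta$pop_id
  if (any(rowSums(x) == 0))
    stop("all-zero land-cover vector for: ",
         paste(meta$pop_id[rowSums(x) == 0], collapse = ", "),
         " (Bray-Curtis undefined)")
  m <- as.matrix(vegan::vegdist(x, method = "bray"))
  d <- dist_matrix_obj(m, kind = "bray_curtis")
  attr(d, "radius") <- radius
  attr(d, "classes") <- classes
  d
}
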