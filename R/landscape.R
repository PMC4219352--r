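#' Great-circle distances (km)
#'
#' Haversine distance on a 6371-km sphere between all coordinate pairs.
#'
#' @param lon,lat coordinate vectors in decimal degrees.
#' @param labels optional labels for the resulting matrix.
#' @return [dist_matrix] in kilometres.
#' @export
haversine_km <- function(lon, lat, labels = NULL) {
  if (anyNA(lon) || anyNA(lat)) {
    bad <- which(is.na(lon) | is.na(lat))
    stop("missing coordinates for: ",
         paste(if (is.null(labels)) bad else labels[bad], collapse = ", "),
         call. = FALSE)
  }
  r <- 6371
  phi <- lat * pi / 180; lam <- lon * pi / 180
  n <- length(lon)
  dphi <- outer(phi, phi, "-") / 2
  dlam <- outer(lam, lam, "-") / 2
  a <- sin(dphi)^2 + outer(cos(phi), cos(phi)) * sin(dlam)^2
  d <- 2 * r * asin(pmin(sqrt(a), 1))
  if (is.null(labels)) labels <- as.character(seq_len(n))
  dimnames(d) <- list(labels, labels)
  dist_matrix(d)
}

#' Assign inter-individual distances to Delaunay edge midpoints
#'
#' The value at an edge midpoint is the mean inter-individual distance over
#' all sample pairs spanning the edge's two sites. Edges with no cross-site
#' sample pair are dropped with a warning.
#'
#' @param net a [build_connectivity] network.
#' @param dm [dist_matrix] of inter-individual distances.
#' @param sample_site_map named character vector: sample id -> site id.
#' @return data.frame with columns \code{lon}, \code{lat}, \code{value},
#'   \code{from}, \code{to}.
#' @export
edge_midpoint_values <- function(net, dm, sample_site_map) {
  stopifnot(inherits(net, "connectivity"))
  d <- as.matrix(dm)
  ids <- rownames(d)
  site <- sample_site_map[ids]
  out <- lapply(seq_len(nrow(net$edges)), function(k) {
    s1 <- net$edges$from[k]; s2 <- net$edges$to[k]
    i <- which(site == s1); j <- which(site == s2)
    if (!length(i) || !length(j)) return(NULL)
    data.frame(lon = net$edges$mid_lon[k], lat = net$edges$mid_lat[k],
               value = mean(d[i, j, drop = FALSE]),
               from = s1, to = s2, stringsAsFactors = FALSE)
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0)
    warning(dropped, " edge(s) without cross-site sample pairs dropped")
  res <- do.call(rbind, out)
  if (is.null(res)) stop("no edge has cross-site sample pairs", call. = FALSE)
  res
}

#' Residualize midpoint values against geographic distance
#'
#' Ordinary least squares of the midpoint value on the great-circle
#' distance (km) between the edge's two sites; returns observed - fitted.
#' Used to remove the trivial isolation-by-distance trend before
#' interpolating distance surfaces.
#'
#' @param midpoints data.frame from [edge_midpoint_values].
#' @param site_coords data.frame with \code{site_id}, \code{lon}, \code{lat}.
#' @return \code{midpoints} with \code{value} replaced by the residual (the
#'   raw value is kept as \code{raw_value}; the fitted model is attached as
#'   attribute \code{fit}).
#' @export
residualize <- function(midpoints, site_coords) {
  if (nrow(midpoints) < 3) stop("need >= 3 midpoints", call. = FALSE)
  gd <- haversine_km(site_coords$lon, site_coords$lat, site_coords$site_id)
  pred <- gd[cbind(midpoints$from, midpoints$to)]
  if (stats::sd(pred) < 1e-12) {
    warning("zero variance in geographic distances: values passed through")
    midpoints$raw_value <- midpoints$value
    return(midpoints)
  }
  fit <- stats::lm(midpoints$value ~ pred)
  midpoints$raw_value <- midpoints$value
  midpoints$value <- stats::residuals(fit)
  attr(midpoints, "fit") <- fit
  midpoints
}

# Ray-casting point-in-polygon (polygon as closed ring matrix [lon,lat]).
point_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]; xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Convex hull of points expanded by `margin` fraction about its centroid.
expanded_hull <- function(lon, lat, margin = 0.05) {
  h <- grDevices::chull(lon, lat)
  cx <- mean(lon[h]); cy <- mean(lat[h])
  cbind(cx + (lon[h] - cx) * (1 + margin), cy + (lat[h] - cy) * (1 + margin))
}

#' Inverse-distance-weighted interpolation surface
#'
#' Grid value \eqn{\hat v = \sum w_i v_i / \sum w_i} with
#' \eqn{w_i = 1/d_i^a}; a node coinciding with a data point (within
#' \code{coincide_eps} in degree-equivalent units) takes that point's value
#' exactly. Distances are planar, on an equirectangular projection about
#' the mean latitude of the data. Cells outside the convex hull of the
#' points (expanded by \code{margin}) are masked unless
#' \code{mask_hull = FALSE}.
#'
#' @param points data.frame with \code{lon}, \code{lat}, \code{value}.
#' @param a distance-weighting exponent (> 0), default 2.
#' @param grid_cols number of grid columns (>= 2), default 150.
#' @param margin bounding-box and hull margin, as a fraction.
#' @param mask_hull mask cells outside the expanded convex hull?
#' @param bbox optional c(lon_min, lon_max, lat_min, lat_max); must enclose
#'   the points. Default: point bounding box plus margin.
#' @param coincide_eps node/point coincidence tolerance (degrees).
#' @return A [surface].
#' @export
idw_surface <- function(points, a = 2, grid_cols = 150, margin = 0.05,
                        mask_hull = TRUE, bbox = NULL, coincide_eps = 1e-9) {
  if (nrow(points) < 1) stop("empty point set", call. = FALSE)
  if (a <= 0) stop("weighting exponent must be > 0", call. = FALSE)
  if (grid_cols < 2) stop("grid_cols must be >= 2", call. = FALSE)
  lon <- points$lon; lat <- points$lat; val <- points$value
  if (is.null(bbox)) {
    mx <- margin * max(diff(range(lon)), 1e-6)
    my <- margin * max(diff(range(lat)), 1e-6)
    bbox <- c(min(lon) - mx, max(lon) + mx, min(lat) - my, max(lat) + my)
  }
  if (any(lon < bbox[1] | lon > bbox[2] | lat < bbox[3] | lat > bbox[4]))
    stop("bbox does not enclose all points", call. = FALSE)
  cellsize <- (bbox[2] - bbox[1]) / grid_cols
  nrows <- max(2L, ceiling((bbox[4] - bbox[3]) / cellsize))
  glon <- bbox[1] + (seq_len(grid_cols) - 0.5) * cellsize
  glat <- bbox[3] + (rev(seq_len(nrows)) - 0.5) * cellsize   # north first
  lat0 <- mean(lat)
  pxy <- equirect_project(lon, lat, lat0)
  grid <- expand.grid(lon = glon, lat = glat)               # row-major per lat band
  gxy <- equirect_project(grid$lon, grid$lat, lat0)
  d <- sqrt(outer(gxy[, 1], pxy[, 1], "-")^2 + outer(gxy[, 2], pxy[, 2], "-")^2)
  hit <- d < coincide_eps
  w <- 1 / d^a
  w[hit] <- NA                      # handled exactly below
  v <- as.vector((ifelse(is.na(w), 0, w) %*% val) /
                   rowSums(w, na.rm = TRUE))
  coincident <- which(rowSums(hit) > 0)
  if (length(coincident))
    v[coincident] <- val[apply(hit[coincident, , drop = FALSE], 1, which.max)]
  vm <- matrix(v, nrow = nrows, ncol = grid_cols, byrow = TRUE)
  mask <- matrix(FALSE, nrows, grid_cols)
  if (mask_hull && length(unique(paste(lon, lat))) >= 3) {
    poly <- expanded_hull(lon, lat, margin)
    inside <- point_in_poly(grid$lon, grid$lat, poly)
    mask <- matrix(!inside, nrow = nrows, ncol = grid_cols, byrow = TRUE)
  }
  surface(vm, origin = c(bbox[1], bbox[3]), cellsize = cellsize, mask = mask)
}

#' Barycenters of geographic groups
#'
#' The coordinate of a group is the barycenter (plain mean) of the distinct
#' sampling places belonging to it.
#'
#' @param samples a sample table.
#' @return data.frame with \code{geo_group}, \code{lon}, \code{lat},
#'   \code{n_sites}.
#' @export
group_barycenters <- function(samples) {
  sites <- unique(samples[, c("site_id", "lon", "lat", "geo_group")])
  agg <- stats::aggregate(cbind(lon, lat) ~ geo_group, data = sites, FUN = mean)
  agg$n_sites <- as.vector(table(sites$geo_group)[agg$geo_group])
  agg
}

#' Diversity / variability surface over group barycenters
#'
#' IDW interpolation of per-group scalar values (nucleotide diversity
#' averaged over loci, or MMS variability) placed at the group barycenters.
#' Groups with an undefined value (e.g. single-sample groups) are excluded
#' with a warning.
#'
#' @param values named numeric vector: geo_group -> value.
#' @param barycenters data.frame from [group_barycenters].
#' @inheritParams idw_surface
#' @return A [surface].
#' @export
diversity_surface <- function(values, barycenters, a = 2, grid_cols = 150,
                              margin = 0.05, mask_hull = TRUE, bbox = NULL) {
  v <- values[barycenters$geo_group]
  if (anyNA(v)) {
    warning("group(s) with undefined value excluded: ",
            paste(barycenters$geo_group[is.na(v)], collapse = ", "))
  }
  keep <- !is.na(v)
  if (!any(keep)) stop("no group with a finite value", call. = FALSE)
  pts <- data.frame(lon = barycenters$lon[keep], lat = barycenters$lat[keep],
                    value = as.numeric(v[keep]))
  idw_surface(pts, a = a, grid_cols = grid_cols, margin = margin,
              mask_hull = mask_hull && nrow(pts) >= 3, bbox = bbox)
}
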