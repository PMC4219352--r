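# Planar Delaunay triangulation (Bowyer-Watson). Coordinates are expected
# to be pre-projected; callers project lon/lat with equirect_project().

orient2d <- function(a, b, c) {
  (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
}

# > 0 when p lies strictly inside the circumcircle of ccw triangle (a,b,c)
incircle <- function(a, b, c, p) {
  if (orient2d(a, b, c) < 0) { tmp <- b; b <- c; c <- tmp }
  m <- rbind(c(a[1] - p[1], a[2] - p[2], (a[1] - p[1])^2 + (a[2] - p[2])^2),
             c(b[1] - p[1], b[2] - p[2], (b[1] - p[1])^2 + (b[2] - p[2])^2),
             c(c[1] - p[1], c[2] - p[2], (c[1] - p[1])^2 + (c[2] - p[2])^2))
  det(m)
}

delaunay_triangles <- function(xy) {
  n <- nrow(xy)
  span <- max(apply(xy, 2, function(v) diff(range(v))), 1e-9)
  cx <- mean(range(xy[, 1])); cy <- mean(range(xy[, 2]))
  big <- 50 * span
  pts <- rbind(xy,
               c(cx - 2 * big, cy - big),
               c(cx + 2 * big, cy - big),
               c(cx, cy + 2 * big))
  tris <- list(c(n + 1L, n + 2L, n + 3L))
  for (i in seq_len(n)) {
    p <- pts[i, ]
    bad <- vapply(tris, function(t)
      incircle(pts[t[1], ], pts[t[2], ], pts[t[3], ], p) > 0, logical(1))
    # boundary of the cavity: edges of bad triangles not shared by two of them
    edges <- do.call(rbind, lapply(tris[bad], function(t)
      rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1, 3)]))))
    if (is.null(edges)) next
    key <- paste(edges[, 1], edges[, 2])
    boundary <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- c(tris[!bad],
              lapply(seq_len(nrow(boundary)), function(k) c(boundary[k, ], i)))
  }
  keep <- vapply(tris, function(t) all(t <= n), logical(1))
  do.call(rbind, tris[keep])
}

# Equirectangular projection about the mean latitude: planar coordinates in
# "degree-equivalent" units (x compressed by cos(mean lat)).
equirect_project <- function(lon, lat, lat0 = mean(lat)) {
  cbind(x = lon * cos(lat0 * pi / 180), y = lat)
}

#' Delaunay connectivity network of sampling sites
#'
#' Builds the planar Delaunay triangulation of the sites (equirectangular
#' projection about the mean latitude) and records each edge with the
#' midpoint of its endpoints — the landscape coordinates at which
#' inter-site distance values are later assigned. Duplicate coordinates are
#' jittered by a small epsilon with a warning.
#'
#' @param site_coords data.frame with columns \code{site_id}, \code{lon},
#'   \code{lat} (>= 3 non-collinear sites).
#' @param jitter_eps jitter (degrees) applied to exactly duplicated
#'   coordinates.
#' @return Object of class \code{connectivity}: \code{sites} (the input)
#'   and \code{edges} (site-id pairs with midpoint lon/lat).
#' @export
build_connectivity <- function(site_coords, jitter_eps = 1e-6) {
  df <- as.data.frame(site_coords)
  stopifnot(all(c("site_id", "lon", "lat") %in% names(df)))
  if (nrow(df) < 3) stop("need >= 3 sites", call. = FALSE)
  dup <- duplicated(df[, c("lon", "lat")])
  if (any(dup)) {
    warning(sum(dup), " duplicated coordinate(s) jittered by ", jitter_eps, " deg")
    df$lon[dup] <- df$lon[dup] + jitter_eps * seq_len(sum(dup))
    df$lat[dup] <- df$lat[dup] + jitter_eps * seq_len(sum(dup))
  }
  xy <- equirect_project(df$lon, df$lat)
  ors <- utils::combn(nrow(df), 3)
  if (all(apply(ors, 2, function(ix)
    abs(orient2d(xy[ix[1], ], xy[ix[2], ], xy[ix[3], ])) < 1e-12)))
    stop("all sites collinear: no triangulation", call. = FALSE)
  tris <- delaunay_triangles(xy)
  e <- unique(do.call(rbind, lapply(seq_len(nrow(tris)), function(k) {
    t <- tris[k, ]
    rbind(sort(t[1:2]), sort(t[2:3]), sort(t[c(1, 3)]))
  })))
  edges <- data.frame(from = df$site_id[e[, 1]], to = df$site_id[e[, 2]],
                      mid_lon = (df$lon[e[, 1]] + df$lon[e[, 2]]) / 2,
                      mid_lat = (df$lat[e[, 1]] + df$lat[e[, 2]]) / 2,
                      stringsAsFactors = FALSE)
  structure(list(sites = df, edges = edges), class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat("<connectivity>", nrow(x$sites), "sites,", nrow(x$edges), "Delaunay edges\n")
  invisible(x)
}
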