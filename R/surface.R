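#' Interpolated landscape surface
#'
#' A regular lon/lat grid of interpolated values with an optional mask for
#' cells outside the interpolation domain (e.g. outside the convex hull of
#' the sampling sites). Values are stored as an \code{n_rows x n_cols}
#' matrix whose first row is the *northernmost* row, matching the on-disk
#' ESRI ASCII layout.
#'
#' @param values numeric matrix (rows = latitude bands, north first).
#' @param origin numeric length-2, (lon, lat) of the lower-left corner.
#' @param cellsize cell size in degrees (> 0).
#' @param mask logical matrix, TRUE = cell outside domain (carries no value).
#' @return object of class \code{surface}.
#' @export
surface <- function(values, origin, cellsize, mask = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(cellsize) || cellsize <= 0) stop("cellsize must be > 0", call. = FALSE)
  if (length(origin) != 2) stop("origin must be (lon, lat)", call. = FALSE)
  if (is.null(mask)) mask <- is.na(values)
  mask <- mask | is.na(values)
  values[mask] <- NA_real_
  structure(list(values = values, origin = as.numeric(origin),
                 cellsize = as.numeric(cellsize), mask = mask),
            class = "surface")
}

#' @export
print.surface <- function(x, ...) {
  cat("<surface>", nrow(x$values), "x", ncol(x$values), "cells,",
      format(x$cellsize, digits = 4), "deg; origin (",
      paste(format(x$origin, digits = 6), collapse = ", "), ");",
      sum(!x$mask), "valid cells\n")
  invisible(x)
}

# Cell-centre coordinates, same orientation as $values.
surface_cell_centers <- function(s) {
  nr <- nrow(s$values); nc <- ncol(s$values)
  lon <- s$origin[1] + (seq_len(nc) - 0.5) * s$cellsize
  lat <- s$origin[2] + (nr - seq_len(nr) + 0.5) * s$cellsize
  list(lon = lon, lat = lat)
}

#' Write a surface as an ESRI ASCII grid
#'
#' @param s a [surface].
#' @param path output path (conventionally \code{.asc}).
#' @param nodata value written for masked cells.
#' @return \code{path}, invisibly.
#' @export
write_ascii_grid <- function(s, path, nodata = -9999) {
  stopifnot(inherits(s, "surface"))
  v <- s$values
  v[s$mask] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)),
               paste("nrows", nrow(v)),
               paste("xllcorner", format(s$origin[1], digits = 15)),
               paste("yllcorner", format(s$origin[2], digits = 15)),
               paste("cellsize", format(s$cellsize, digits = 15)),
               paste("NODATA_value", nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII grid written by [write_ascii_grid]
#' @param path grid path.
#' @return a [surface].
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "[[:space:]]+")
  keys <- tolower(vapply(hdr, `[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(vals) <- keys
  v <- as.matrix(utils::read.table(text = lines[-(1:6)]))
  dimnames(v) <- NULL
  stopifnot(nrow(v) == vals["nrows"], ncol(v) == vals["ncols"])
  mask <- v == vals["nodata_value"]
  v[mask] <- NA_real_
  surface(v, origin = c(vals["xllcorner"], vals["yllcorner"]),
          cellsize = vals["cellsize"], mask = mask)
}
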