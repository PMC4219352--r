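#' Read the sample metadata table
#'
#' Reads the CSV joining genetic and chemical data: one row per individual
#' with its sampling site, coordinates (decimal degrees, WGS84 assumed),
#' geographic group, and colour-pattern label. Unknown columns are kept
#' untouched as opaque metadata.
#'
#' Required columns: \code{id}, \code{site_id}, \code{lat}, \code{lon},
#' \code{geo_group}, \code{colour_label}.
#'
#' @param path CSV path with a header row.
#' @return A \code{data.frame} of class \code{sample_table}.
#' @export
read_sample_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_table(df)
}

#' Validate a sample table
#'
#' @param df data.frame with the columns documented in [read_sample_table].
#' @return \code{df} with class \code{sample_table} prepended.
#' @export
validate_sample_table <- function(df) {
  req <- c("id", "site_id", "lat", "lon", "geo_group", "colour_label")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("sample table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id))
    stop("duplicate sample id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "), call. = FALSE)
  for (cc in c("lat", "lon")) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    if (anyNA(v)) stop("unparseable ", cc, " for sample(s): ",
                       paste(df$id[is.na(v)], collapse = ", "), call. = FALSE)
    df[[cc]] <- v
  }
  if (any(df$lat < -90 | df$lat > 90))
    stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(df$lon < -180 | df$lon > 180))
    stop("longitude outside [-180, 180]", call. = FALSE)
  if (any(!nzchar(df$geo_group)))
    stop("empty geo_group entries", call. = FALSE)
  if (!inherits(df, "sample_table")) class(df) <- c("sample_table", class(df))
  df
}

#' Read a compositional chemical-profile matrix
#'
#' Reads the samples-by-compounds matrix of relative amounts (%), as
#' exported from GC quantification: first column sample ids, remaining
#' columns compounds. Rows whose total departs from 100% by more than
#' \code{tol} are flagged (attribute \code{flagged}), not rejected — the
#' downstream filter and transform do not require exact closure.
#'
#' @param path CSV path.
#' @param tol closure tolerance on the row sum, in percentage points.
#' @return A numeric matrix of class \code{chem_profile} with sample ids as
#'   row names, compound ids as column names, and attribute \code{flagged}
#'   naming rows that failed the closure check.
#' @export
read_chem_matrix <- function(path, tol = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  chem_profile(m, tol = tol)
}

#' @rdname read_chem_matrix
#' @param m numeric matrix of relative amounts (samples x compounds).
#' @export
chem_profile <- function(m, tol = 0.5) {
  if (anyNA(m)) stop("missing values in chemical matrix", call. = FALSE)
  if (any(m < 0)) stop("negative relative amounts", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate sample ids", call. = FALSE)
  rs <- rowSums(m)
  flagged <- rownames(m)[abs(rs - 100) > tol]
  structure(m, class = c("chem_profile", class(m)), flagged = flagged)
}

#' Construct/validate a labelled distance matrix
#'
#' The common carrier for genetic p-distances, Bray-Curtis chemical
#' distances, great-circle geographic distances and binary colour distances:
#' a symmetric matrix with zero diagonal, finite entries and row/column
#' labels.
#'
#' @param m square numeric matrix with matching dimnames.
#' @return \code{m}, validated, with class \code{dist_matrix}.
#' @export
dist_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix not square", call. = FALSE)
  if (is.null(rownames(m))) stop("distance matrix needs labels", call. = FALSE)
  if (is.null(colnames(m))) colnames(m) <- rownames(m)
  if (!identical(rownames(m), colnames(m)))
    stop("row/column labels disagree", call. = FALSE)
  if (any(!is.finite(m))) stop("non-finite distance entries", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8) stop("distance matrix not symmetric", call. = FALSE)
  m <- (m + t(m)) / 2
  if (any(abs(diag(m)) > 1e-12)) stop("non-zero diagonal", call. = FALSE)
  diag(m) <- 0
  class(m) <- c("dist_matrix", "matrix", "array")
  m
}

# Align two labelled distance matrices onto their common labels, preserving
# the order of the first.
align_dist <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  if (length(common) < nrow(a) || length(common) < nrow(b))
    message(sprintf("distance matrices share %d of %d/%d labels",
                    length(common), nrow(a), nrow(b)))
  list(a = a[common, common, drop = FALSE], b = b[common, common, drop = FALSE])
}

#' Report sample overlap across data sources
#'
#' Genetic, chemical and metadata tables typically cover overlapping but
#' unequal sample sets (collected > sequenced > chemically profiled). This
#' reports, per source, which samples are missing relative to the union —
#' joins in the pipeline are always explicit, never silent drops.
#'
#' @param ... named character vectors of sample ids (e.g.
#'   \code{genetic = ..., chemical = ..., table = ...}).
#' @return A list with \code{union}, \code{intersection} and a per-source
#'   list \code{missing}.
#' @export
sample_overlap <- function(...) {
  sets <- list(...)
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all id sets must be named", call. = FALSE)
  u <- Reduce(union, sets)
  list(union = u,
       intersection = Reduce(intersect, sets),
       missing = lapply(sets, function(s) setdiff(u, s)))
}

#' Write a statistics table as TSV with a reproducibility header
#'
#' Every statistics output embeds the RNG seed and the parameter set used,
#' as commented header lines, so a run can be reproduced from its outputs.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @param seed integer seed used for the computation (or NA).
#' @param params named list of parameters to record.
#' @return \code{path}, invisibly.
#' @export
write_stats_tsv <- function(df, path, seed = NA, params = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# seed: %s", as.character(seed)), con)
  if (length(params))
    writeLines(sprintf("# param %s: %s", names(params),
                       vapply(params, function(p) paste(format(p), collapse = ","),
                              character(1))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_stats_tsv]
#' @param path TSV path.
#' @return data.frame (header metadata in attribute \code{metadata}).
#' @export
read_stats_tsv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  df <- utils::read.delim(text = lines[!grepl("^#", lines)],
                          stringsAsFactors = FALSE)
  attr(df, "metadata") <- meta
  df
}
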