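#' Aligned sequences for one locus
#'
#' Container for a per-locus nucleotide alignment. Sequences are stored as
#' uppercase strings over the alphabet \code{A,C,G,T,N,-}; any other IUPAC
#' ambiguity code is mapped to \code{N} with a warning (consensus sequences
#' in the intended workflow carry no ambiguity).
#'
#' @param sequences character vector of equal-length nucleotide strings.
#' @param sample_ids character vector of unique sample identifiers, same
#'   length as \code{sequences}.
#' @param locus_id single string naming the locus (e.g. \code{"COI"}).
#' @return An object of class \code{seq_alignment}: a list with elements
#'   \code{locus_id}, \code{sample_ids}, \code{sequences} and \code{length}
#'   (alignment length in bp).
#' @export
seq_alignment <- function(sequences, sample_ids, locus_id = "locus") {
  if (length(sequences) == 0L) stop("alignment is empty", call. = FALSE)
  if (length(sequences) != length(sample_ids))
    stop("sequences and sample_ids differ in length", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in alignment: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  sequences <- toupper(as.character(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop("unequal sequence lengths (", paste(sort(unique(lens)), collapse = ", "),
         "): input is not an alignment", call. = FALSE)
  if (lens[1] == 0L) stop("alignment length must be > 0", call. = FALSE)
  bad <- grepl("[^ACGTN-]", sequences)
  if (any(bad)) {
    warning("ambiguity codes other than N mapped to N")
    sequences[bad] <- gsub("[^ACGTN-]", "N", sequences[bad])
  }
  structure(
    list(locus_id = as.character(locus_id)[1],
         sample_ids = as.character(sample_ids),
         sequences = sequences,
         length = lens[1]),
    class = "seq_alignment")
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("<seq_alignment> locus", x$locus_id, "-", length(x$sample_ids),
      "sequences x", x$length, "bp\n")
  invisible(x)
}

# Character matrix view (samples x sites); row names are sample ids.
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$sequences, "", fixed = TRUE))
  rownames(m) <- aln$sample_ids
  m
}

#' Read a FASTA alignment
#'
#' Parses a FASTA file into a [seq_alignment]. Sequences are uppercased on
#' read; files whose records differ in length are rejected, since every
#' downstream statistic assumes aligned sites.
#'
#' @param path path to a FASTA file.
#' @param locus_id locus name attached to the alignment; defaults to the
#'   file name without extension.
#' @return A [seq_alignment].
#' @export
read_fasta_alignment <- function(path, locus_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0) stop("empty FASTA file: ", path, call. = FALSE)
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- vapply(as.character(recs),
                 function(s) paste(s, collapse = ""), character(1))
  if (is.null(locus_id))
    locus_id <- sub("\\.[^.]*$", "", basename(path))
  seq_alignment(seqs, names(recs), locus_id)
}

#' Write a FASTA alignment
#'
#' @param aln a [seq_alignment].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "seq_alignment"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", aln$sample_ids, "\n", aln$sequences), con)
  invisible(path)
}
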