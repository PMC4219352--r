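#' Collapse an alignment into haplotypes
#'
#' Haplotype identity is exact string match after uppercasing (the intended
#' alignments carry no indels, so no indel-aware collapsing is attempted).
#' Haplotype ids are stable: numbered by first occurrence in the alignment.
#'
#' @param aln a [seq_alignment].
#' @param groups optional named character vector mapping sample id to a
#'   group label; if given, per-group haplotype counts are tabulated.
#' @return An object of class \code{haplotype_set}: list with
#'   \code{locus_id}, \code{haplotypes} (distinct sequences, named
#'   \code{H1..Hk}), \code{assignment} (sample id -> haplotype id) and
#'   \code{counts} (overall, or group x haplotype table when \code{groups}
#'   is supplied).
#' @export
collapse_haplotypes <- function(aln, groups = NULL) {
  stopifnot(inherits(aln, "seq_alignment"))
  uniq <- unique(aln$sequences)
  hap_ids <- paste0("H", seq_along(uniq))
  names(uniq) <- hap_ids
  assignment <- hap_ids[match(aln$sequences, uniq)]
  names(assignment) <- aln$sample_ids
  if (is.null(groups)) {
    counts <- table(factor(assignment, levels = hap_ids))
  } else {
    g <- groups[aln$sample_ids]
    if (anyNA(g)) stop("groups missing for sample(s): ",
                       paste(aln$sample_ids[is.na(g)], collapse = ", "),
                       call. = FALSE)
    counts <- table(group = g, haplotype = factor(assignment, levels = hap_ids))
  }
  structure(list(locus_id = aln$locus_id, haplotypes = uniq,
                 assignment = assignment, counts = counts),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("<haplotype_set> locus", x$locus_id, "-", length(x$haplotypes),
      "haplotypes among", length(x$assignment), "samples\n")
  invisible(x)
}

#' Count parsimony-informative sites
#'
#' A site is parsimony informative when at least two distinct nucleotide
#' states each occur in at least two sequences. Gaps and \code{N} are not
#' counted as states.
#'
#' @param aln a [seq_alignment].
#' @return Integer count of informative sites.
#' @export
count_parsimony_informative <- function(aln) {
  m <- aln_matrix(aln)
  sum(apply(m, 2, function(col) {
    tab <- table(col[col %in% c("A", "C", "G", "T")])
    sum(tab >= 2) >= 2
  }))
}

#' Haplotype diversity (Nei's unbiased h)
#'
#' \eqn{\hat h = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)} where
#' \eqn{p_i} are haplotype frequencies.
#'
#' @param counts integer vector of haplotype counts.
#' @param n sample size; defaults to \code{sum(counts)}.
#' @return h in \[0, 1\].
#' @export
haplotype_diversity <- function(counts, n = sum(counts)) {
  counts <- counts[counts > 0]
  if (n < 2) stop("haplotype diversity undefined for n < 2", call. = FALSE)
  if (sum(counts) != n) stop("counts do not sum to n", call. = FALSE)
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

# Pairwise mismatch and comparable-site counts for one alignment,
# pairwise deletion of sites with gap/N in either member. O(n^2) via
# indicator cross-products.
mismatch_counts <- function(aln) {
  m <- aln_matrix(aln)
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)
  compared <- tcrossprod(valid * 1)
  matches <- matrix(0, nrow(m), nrow(m))
  for (b in c("A", "C", "G", "T")) {
    ind <- (m == b) * 1
    matches <- matches + tcrossprod(ind)
  }
  mism <- compared - matches
  dimnames(mism) <- dimnames(compared) <- list(aln$sample_ids, aln$sample_ids)
  list(mismatches = mism, compared = compared)
}

#' Nucleotide diversity (pi)
#'
#' Mean per-site pairwise difference:
#' \eqn{\pi = \frac{2}{n(n-1)} \sum_{i<j} d_{ij}/L_{ij}}, with pairwise
#' deletion — \eqn{L_{ij}} counts only sites where both members carry an
#' unambiguous base. Units: substitutions per site.
#'
#' @param aln a [seq_alignment] with at least 2 sequences.
#' @return pi (numeric scalar).
#' @export
nucleotide_diversity <- function(aln) {
  n <- length(aln$sample_ids)
  if (n < 2) stop("nucleotide diversity undefined for n < 2", call. = FALSE)
  mc <- mismatch_counts(aln)
  ut <- upper.tri(mc$compared)
  cmp <- mc$compared[ut]
  d <- mc$mismatches[ut]
  if (any(cmp == 0)) {
    warning("sequence pair(s) share no comparable sites; excluded")
    d <- d[cmp > 0]; cmp <- cmp[cmp > 0]
  }
  if (!length(cmp)) stop("no comparable pairs", call. = FALSE)
  sum(d / cmp) / (n * (n - 1) / 2)
}

#' Per-locus and multi-locus pairwise p-distances
#'
#' Per locus, the p-distance between two samples is the number of
#' mismatches divided by the number of comparable sites (pairwise
#' deletion). With several loci, a pair's distance is the unweighted mean
#' of its per-locus p-distances over the loci in which both samples occur —
#' the "averaged p-distances over loci" used for cartography and the Mantel
#' layer.
#'
#' @param alns a [seq_alignment] or list of them (one per locus).
#' @return A [dist_matrix] over the union of samples; a pair sharing no
#'   locus (or no comparable sites) raises an error naming the pair.
#' @export
pairwise_p_distance <- function(alns) {
  if (inherits(alns, "seq_alignment")) alns <- list(alns)
  ids <- Reduce(union, lapply(alns, `[[`, "sample_ids"))
  acc <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  nloc <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (aln in alns) {
    mc <- mismatch_counts(aln)
    ok <- mc$compared > 0
    p <- ifelse(ok, mc$mismatches / pmax(mc$compared, 1L), 0)
    idx <- aln$sample_ids
    acc[idx, idx] <- acc[idx, idx] + p
    nloc[idx, idx] <- nloc[idx, idx] + ok
  }
  diag(nloc) <- pmax(diag(nloc), 1L)
  if (any(nloc == 0)) {
    bad <- which(nloc == 0 & upper.tri(nloc), arr.ind = TRUE)
    stop("sample pair(s) share no locus: ",
         paste(ids[bad[, 1]], ids[bad[, 2]], sep = "/", collapse = ", "),
         call. = FALSE)
  }
  dist_matrix(acc / nloc)
}

#' Pairwise mismatch-count matrix for AMOVA
#'
#' The squared inter-individual molecular distance used throughout the
#' AMOVA/SAMOVA layer: number of nucleotide mismatches (pairwise deletion),
#' unscaled.
#'
#' @param aln a [seq_alignment].
#' @return A [dist_matrix] of mismatch counts.
#' @export
pairwise_mismatch_matrix <- function(aln) {
  dist_matrix(mismatch_counts(aln)$mismatches)
}

#' Molecular-clock divergence time
#'
#' Converts a percentage sequence divergence into an age under a constant
#' clock (default 2% divergence per million years, the rate commonly
#' applied to insect mitochondrial DNA).
#'
#' @param divergence_percent pairwise divergence in percent (>= 0).
#' @param rate_percent_per_myr clock rate, percent divergence per Myr (> 0).
#' @return Age in millions of years (exact division; no rounding).
#' @export
clock_divergence_time <- function(divergence_percent, rate_percent_per_myr = 2) {
  if (any(divergence_percent < 0)) stop("divergence must be >= 0", call. = FALSE)
  if (rate_percent_per_myr <= 0) stop("clock rate must be > 0", call. = FALSE)
  divergence_percent / rate_percent_per_myr
}

#' Round half away from zero
#'
#' Decimal reporting convention used for published summaries: exact halves
#' round away from zero (so 0.505 -> 0.51 at 2 decimals), unlike base
#' \code{round()}, which follows IEEE half-to-even on the binary
#' representation.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Diversity statistics per geographic group
#'
#' Tabulates, per geographic group and locus: sample size, haplotype count,
#' haplotype diversity h and nucleotide diversity pi. Groups with a single
#' sample get NA diversities (undefined).
#'
#' @param alns list of [seq_alignment] (one per locus).
#' @param samples a sample table ([read_sample_table]) or named character
#'   vector sample id -> geo_group.
#' @return data.frame with columns locus, geo_group, n, n_haplotypes, h, pi.
#' @export
diversity_by_group <- function(alns, samples) {
  if (inherits(alns, "seq_alignment")) alns <- list(alns)
  groups <- if (is.data.frame(samples))
    stats::setNames(samples$geo_group, samples$id) else samples
  out <- list()
  for (aln in alns) {
    g <- groups[aln$sample_ids]
    if (anyNA(g)) stop("geo_group missing for sample(s) at locus ", aln$locus_id,
                       call. = FALSE)
    for (gg in sort(unique(g))) {
      keep <- which(g == gg)
      sub <- seq_alignment(aln$sequences[keep], aln$sample_ids[keep], aln$locus_id)
      hs <- collapse_haplotypes(sub)
      n <- length(keep)
      out[[length(out) + 1L]] <- data.frame(
        locus = aln$locus_id, geo_group = gg, n = n,
        n_haplotypes = length(hs$haplotypes),
        h = if (n >= 2) haplotype_diversity(as.integer(hs$counts)) else NA_real_,
        pi = if (n >= 2) nucleotide_diversity(sub) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
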