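#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration on a labelled distance matrix (delegated to
#' \code{ape::nj}); any negative branch produced on near-degenerate input
#' is clamped to zero with the deficit moved onto its sister branch, so
#' leaf-to-leaf path lengths are preserved.
#'
#' @param dm a [dist_matrix] (or symmetric labelled matrix) over >= 3 taxa.
#' @return An \code{ape::phylo} tree (unrooted).
#' @export
neighbor_joining <- function(dm) {
  m <- as.matrix(dm)
  if (nrow(m) < 3) stop("need >= 3 taxa", call. = FALSE)
  if (any(!is.finite(m))) stop("missing/non-finite distances", call. = FALSE)
  tr <- ape::nj(stats::as.dist(m))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    deficit <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sib <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sib)) tr$edge.length[sib[1]] <- tr$edge.length[sib[1]] + deficit
    tr$edge.length[e] <- 0
  }
  tr
}

# Resample alignment columns with replacement (one bootstrap pseudo-locus).
resample_sites <- function(mat, idx) {
  sub <- mat[, idx, drop = FALSE]
  apply(sub, 1, paste, collapse = "")
}

#' Bootstrap support for a neighbour-joining tree
#'
#' Sites are resampled with replacement within each locus; each replicate's
#' multi-locus averaged p-distance matrix is re-built and passed to the
#' tree builder. Support of an internal edge is the percentage of replicate
#' trees containing the same bipartition, attached as node labels.
#'
#' @param alns a [seq_alignment] or list of them.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer RNG seed.
#' @param builder tree-building function taking a distance matrix.
#' @return The reference tree with \code{node.label} holding percentage
#'   support (root label empty).
#' @export
bootstrap_support <- function(alns, n_reps = 10000, seed = 1,
                              builder = neighbor_joining) {
  if (inherits(alns, "seq_alignment")) alns <- list(alns)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  ref <- builder(pairwise_p_distance(alns))
  mats <- lapply(alns, aln_matrix)
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    boot <- lapply(seq_along(alns), function(k) {
      idx <- sample.int(ncol(mats[[k]]), ncol(mats[[k]]), replace = TRUE)
      seq_alignment(resample_sites(mats[[k]], idx),
                    alns[[k]]$sample_ids, alns[[k]]$locus_id)
    })
    reps[[r]] <- builder(pairwise_p_distance(boot))
  }
  counts <- ape::prop.clades(ref, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  ref$node.label <- round(100 * counts / n_reps, 1)
  ref
}

#' Write a tree as Newick
#' @param tree an \code{ape::phylo}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
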