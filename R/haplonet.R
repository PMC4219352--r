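# Weighted per-site substitution cost: transitions (A<->G, C<->T) cost 1,
# transversions cost `tw`, gap vs base costs `indel_cost`.
site_cost <- function(x, y, tw = 2, indel_cost = tw) {
  if (x == y) return(0)
  if ((x == "-") != (y == "-")) return(indel_cost)
  if ((x %in% c("A", "G") && y %in% c("A", "G")) ||
      (x %in% c("C", "T") && y %in% c("C", "T"))) return(1)
  tw
}

weighted_hamming <- function(a, b, tw = 2, indel_cost = tw) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  diff <- which(sa != sb)
  sum(vapply(diff, function(i) site_cost(sa[i], sb[i], tw, indel_cost), numeric(1)))
}

# Full weighted distance matrix among sequences (character vector).
weighted_dist <- function(seqs, tw = 2, indel_cost = tw) {
  n <- length(seqs)
  d <- matrix(0, n, n)
  if (n > 1)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      d[i, j] <- d[j, i] <- weighted_hamming(seqs[i], seqs[j], tw, indel_cost)
  d
}

# Total length of a minimum spanning tree of a symmetric weight matrix.
mst_length <- function(d) {
  d <- (d + t(d)) / 2
  dimnames(d) <- NULL
  g <- igraph::graph_from_adjacency_matrix(d, mode = "undirected", weighted = TRUE)
  sum(igraph::E(igraph::mst(g, algorithm = "prim"))$weight)
}

# Minimum spanning *network*: all edges belonging to at least one MST.
# Edge (i,j) qualifies iff i and j are in different components of the graph
# restricted to edges strictly shorter than d[i,j] (epsilon relaxes the
# threshold).
msn_edges <- function(d, epsilon = 0) {
  n <- nrow(d)
  comp <- seq_len(n)          # union-find by relabelling (n is small)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  lv <- sort(unique(w))
  keep <- matrix(integer(0), 0, 2)
  for (v in lv) {
    sel <- which(abs(w - v) < 1e-9)
    add <- sel[comp[ut[sel, 1]] != comp[ut[sel, 2]]]
    # epsilon-relaxation: also admit edges joining components already merged
    # at levels within epsilon below v
    if (epsilon > 0) {
      near <- sel[comp[ut[sel, 1]] == comp[ut[sel, 2]] &
                    (d[ut[sel, , drop = FALSE]] - v) <= epsilon]
      add <- union(add, near)
    }
    keep <- rbind(keep, ut[add, , drop = FALSE])
    for (s in sel) {
      c1 <- comp[ut[s, 1]]; c2 <- comp[ut[s, 2]]
      if (c1 != c2) comp[comp == c2] <- c1
    }
  }
  keep
}

# Consensus (median) sequence of three haplotypes: per differing site the
# majority state; three-way ties resolved toward the state minimising the
# summed weighted cost to the triplet's states, then lexicographically.
triplet_median <- function(s1, s2, s3, tw = 2, indel_cost = tw) {
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]; c <- strsplit(s3, "")[[1]]
  out <- a
  for (i in which(!(a == b & b == c))) {
    st <- c(a[i], b[i], c[i])
    tab <- table(st)
    if (max(tab) >= 2) {
      out[i] <- names(tab)[which.max(tab)]
    } else {
      cand <- sort(unique(st))
      cost <- vapply(cand, function(s)
        sum(vapply(st, function(t) site_cost(s, t, tw, indel_cost), numeric(1))),
        numeric(1))
      out[i] <- cand[which.min(cost)]   # which.min: first (lexicographic) tie-break
    }
  }
  paste(out, collapse = "")
}

#' Median-joining haplotype network
#'
#' Bandelt-style median-joining construction under a weighted Hamming
#' distance (transitions cost 1, transversions cost
#' \code{transversion_weight}, indels \code{indel_cost}). The algorithm
#' iterates: build the minimum spanning network (all edges of every minimum
#' spanning tree) over the current node set; propose the consensus (median)
#' vector of every node triplet; add the median that most shortens the
#' total minimum-spanning length; stop when no median improves, then prune
#' median vectors whose removal leaves the spanning length unchanged.
#' Median vectors represent undetected or extinct intermediate haplotypes
#' and carry zero observed frequency.
#'
#' @param hset a \code{haplotype_set} from [collapse_haplotypes] (grouped
#'   counts are carried onto the nodes when present).
#' @param epsilon weight-tolerance for admitting extra links into the
#'   spanning network (0 = strict minimum spanning network).
#' @param transversion_weight cost of a transversion relative to a
#'   transition.
#' @param indel_cost cost of a gap/base change; defaults to the
#'   transversion cost.
#' @return An object of class \code{haplo_network}: \code{nodes}
#'   data.frame (id, sequence, freq, is_median), \code{edges} data.frame
#'   (from, to, mutations, weight, sites), and \code{group_counts} (matrix
#'   or NULL).
#' @export
median_joining_network <- function(hset, epsilon = 0, transversion_weight = 2,
                                   indel_cost = transversion_weight) {
  stopifnot(inherits(hset, "haplotype_set"))
  seqs <- unname(hset$haplotypes)
  ids <- names(hset$haplotypes)
  if (length(seqs) < 2) stop("need >= 2 haplotypes", call. = FALSE)
  if (any(grepl("[^ACGT-]", seqs)))
    stop("non-nucleotide states (other than gaps) in haplotypes", call. = FALSE)
  tw <- transversion_weight
  is_median <- rep(FALSE, length(seqs))
  repeat {
    d <- weighted_dist(seqs, tw, indel_cost)
    base_len <- mst_length(d)
    n <- length(seqs)
    best <- NULL; best_gain <- 1e-9
    if (n >= 3) {
      trip <- utils::combn(n, 3)
      cand <- unique(apply(trip, 2, function(ix)
        triplet_median(seqs[ix[1]], seqs[ix[2]], seqs[ix[3]], tw, indel_cost)))
      cand <- setdiff(cand, seqs)
      for (m in cand) {
        dn <- rbind(cbind(d, vapply(seqs, weighted_hamming, numeric(1), b = m,
                                    tw = tw, indel_cost = indel_cost)), 0)
        dn[nrow(dn), ] <- dn[, ncol(dn)]
        gain <- base_len - mst_length(dn)
        if (gain > best_gain) { best_gain <- gain; best <- m }
      }
    }
    if (is.null(best)) break
    seqs <- c(seqs, best)
    ids <- c(ids, paste0("MV", sum(is_median) + 1L))
    is_median <- c(is_median, TRUE)
  }
  # prune medians that no longer shorten the network
  repeat {
    d <- weighted_dist(seqs, tw, indel_cost)
    len <- mst_length(d)
    drop <- NA
    for (k in which(is_median)) {
      if (abs(mst_length(d[-k, -k, drop = FALSE]) - len) < 1e-9) { drop <- k; break }
    }
    if (is.na(drop)) break
    seqs <- seqs[-drop]; ids <- ids[-drop]; is_median <- is_median[-drop]
  }
  d <- weighted_dist(seqs, tw, indel_cost)
  ed <- msn_edges(d, epsilon)
  freq <- integer(length(seqs))
  cnt <- if (is.matrix(hset$counts) || length(dim(hset$counts)) == 2)
    colSums(hset$counts) else hset$counts
  freq[!is_median] <- as.integer(cnt[ids[!is_median]])
  edges <- data.frame(
    from = ids[ed[, 1]], to = ids[ed[, 2]],
    mutations = vapply(seq_len(nrow(ed)), function(k) {
      a <- strsplit(seqs[ed[k, 1]], "")[[1]]; b <- strsplit(seqs[ed[k, 2]], "")[[1]]
      sum(a != b)
    }, numeric(1)),
    weight = d[ed],
    sites = vapply(seq_len(nrow(ed)), function(k) {
      a <- strsplit(seqs[ed[k, 1]], "")[[1]]; b <- strsplit(seqs[ed[k, 2]], "")[[1]]
      paste(which(a != b), collapse = ",")
    }, character(1)),
    stringsAsFactors = FALSE)
  gc <- NULL
  if (length(dim(hset$counts)) == 2) {
    gc <- matrix(0L, nrow(hset$counts), length(ids),
                 dimnames = list(rownames(hset$counts), ids))
    gc[, ids[!is_median]] <- hset$counts[, ids[!is_median]]
  }
  structure(list(locus_id = hset$locus_id,
                 nodes = data.frame(id = ids, sequence = seqs, freq = freq,
                                    is_median = is_median, stringsAsFactors = FALSE),
                 edges = edges, group_counts = gc),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat("<haplo_network> locus", x$locus_id, "-",
      sum(!x$nodes$is_median), "haplotypes +", sum(x$nodes$is_median),
      "median vectors,", nrow(x$edges), "links\n")
  invisible(x)
}

#' Convert a haplotype network to igraph
#' @param net a \code{haplo_network}.
#' @return an \pkg{igraph} graph with node attributes \code{frequency},
#'   \code{is_median} and edge attributes \code{mutations}, \code{weight},
#'   \code{sites}.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "haplo_network"))
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                     vertices = data.frame(
                                       name = net$nodes$id,
                                       frequency = net$nodes$freq,
                                       is_median = net$nodes$is_median))
  if (!is.null(net$group_counts)) {
    comp <- apply(net$group_counts, 2, function(cl)
      paste(sprintf("%s:%d", rownames(net$group_counts), cl)[cl > 0], collapse = ";"))
    g <- igraph::set_vertex_attr(g, "groups", value = comp[igraph::V(g)$name])
  }
  g
}

#' Write a haplotype network as GraphML
#' @param net a \code{haplo_network}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_haplonet_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}
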