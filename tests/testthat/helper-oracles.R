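# Independent brute-force oracles and fixture builders. Everything here is
# deliberately naive (loops, enumeration) so it cannot share a defect with
# the implementation under test.

random_alignment <- function(n, L, locus = "sim", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
    character(1))
  seq_alignment(seqs, sprintf("t%02d", seq_len(n)), locus)
}

# pi by direct per-pair, per-site loops
pi_oracle <- function(aln) {
  chars <- strsplit(aln$sequences, "")
  n <- length(chars)
  tot <- 0; npair <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    a <- chars[[i]]; b <- chars[[j]]
    ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
    if (!any(ok)) next
    tot <- tot + sum(a[ok] != b[ok]) / sum(ok)
    npair <- npair + 1
  }
  tot / (n * (n - 1) / 2)
}

# parsimony-informative sites by per-column state multiset inspection
pis_oracle <- function(aln) {
  chars <- strsplit(aln$sequences, "")
  L <- length(chars[[1]])
  cnt <- 0
  for (s in seq_len(L)) {
    col <- vapply(chars, `[`, character(1), s)
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < 4) next
    tab <- table(col)
    if (sum(tab >= 2) >= 2) cnt <- cnt + 1
  }
  cnt
}

# multi-locus averaged p-distance by per-site loops
pdist_oracle <- function(alns) {
  ids <- Reduce(union, lapply(alns, `[[`, "sample_ids"))
  out <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    ds <- c()
    for (aln in alns) {
      ii <- match(ids[i], aln$sample_ids); jj <- match(ids[j], aln$sample_ids)
      if (is.na(ii) || is.na(jj)) next
      a <- strsplit(aln$sequences[ii], "")[[1]]
      b <- strsplit(aln$sequences[jj], "")[[1]]
      ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
      if (any(ok)) ds <- c(ds, sum(a[ok] != b[ok]) / sum(ok))
    }
    out[i, j] <- out[j, i] <- mean(ds)
  }
  out
}

# AMOVA oracle: definitional SSDs by explicit pair loops, components by
# solving the expected-mean-square linear system.
amova_oracle <- function(d2, pops, groups = NULL) {
  N <- nrow(d2)
  ssd_of <- function(idx) {
    s <- 0
    for (i in idx) for (j in idx) s <- s + d2[i, j]
    s / (2 * length(idx))
  }
  ssd_t <- ssd_of(seq_len(N))
  upop <- unique(pops)
  ssd_wp <- sum(vapply(upop, function(p) ssd_of(which(pops == p)), numeric(1)))
  np <- vapply(upop, function(p) sum(pops == p), numeric(1))
  if (is.null(groups)) {
    P <- length(upop)
    ms_ap <- (ssd_t - ssd_wp) / (P - 1)
    ms_wp <- ssd_wp / (N - P)
    nco <- (N - sum(np^2) / N) / (P - 1)
    sig <- solve(rbind(c(nco, 1), c(0, 1)), c(ms_ap, ms_wp))
    return(list(sigma_a = sig[1], sigma_w = sig[2],
                phi_st = sig[1] / sum(sig)))
  }
  grp_of_ind <- groups[pops]
  ugrp <- unique(groups[upop])
  G <- length(ugrp); P <- length(upop)
  ssd_wg <- sum(vapply(ugrp, function(g) ssd_of(which(grp_of_ind == g)), numeric(1)))
  ms_ag <- (ssd_t - ssd_wg) / (G - 1)
  ms_ap <- (ssd_wg - ssd_wp) / (P - G)
  ms_wp <- ssd_wp / (N - P)
  ng <- vapply(ugrp, function(g) sum(grp_of_ind == g), numeric(1))
  A <- vapply(ugrp, function(g) {
    pp <- upop[groups[upop] == g]
    sum(np[match(pp, upop)]^2) / sum(pops %in% pp)
  }, numeric(1))
  n1 <- (N - sum(A)) / (P - G)
  n2 <- (sum(A) - sum(np^2) / N) / (G - 1)
  n3 <- (N - sum(ng^2) / N) / (G - 1)
  M <- rbind(c(n3, n2, 1), c(0, n1, 1), c(0, 0, 1))
  sig <- solve(M, c(ms_ag, ms_ap, ms_wp))
  tot <- sum(sig)
  list(sigma = sig, phi_ct = sig[1] / tot, phi_sc = sig[2] / (sig[2] + sig[3]),
       phi_st = (sig[1] + sig[2]) / tot)
}

# All minimum spanning trees of a weighted complete graph by subset
# enumeration (n <= 6): returns list of edge matrices.
all_msts <- function(d) {
  n <- nrow(d)
  pairs <- t(utils::combn(n, 2))
  w <- d[pairs]
  subs <- utils::combn(nrow(pairs), n - 1)
  best <- Inf; trees <- list()
  for (k in seq_len(ncol(subs))) {
    sel <- subs[, k]
    # spanning + acyclic check via component merging
    comp <- seq_len(n)
    ok <- TRUE
    for (e in sel) {
      a <- comp[pairs[e, 1]]; b <- comp[pairs[e, 2]]
      if (a == b) { ok <- FALSE; break }
      comp[comp == b] <- a
    }
    if (!ok || length(unique(comp)) != 1) next
    tw <- sum(w[sel])
    if (tw < best - 1e-9) { best <- tw; trees <- list(pairs[sel, , drop = FALSE]) }
    else if (abs(tw - best) < 1e-9) trees <- c(trees, list(pairs[sel, , drop = FALSE]))
  }
  trees
}

# Delaunay edges by O(n^4) empty-circumcircle triple check
delaunay_oracle <- function(xy) {
  n <- nrow(xy)
  circum <- function(a, b, c) {
    ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
    d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
    if (abs(d) < 1e-14) return(NULL)
    ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
             (cx^2 + cy^2) * (ay - by)) / d
    uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
             (cx^2 + cy^2) * (bx - ax)) / d
    c(ux, uy)
  }
  edges <- matrix(integer(0), 0, 2)
  for (tri in utils::combn(n, 3, simplify = FALSE)) {
    ctr <- circum(xy[tri[1], ], xy[tri[2], ], xy[tri[3], ])
    if (is.null(ctr)) next
    r2 <- sum((xy[tri[1], ] - ctr)^2)
    inside <- FALSE
    for (p in setdiff(seq_len(n), tri)) {
      if (sum((xy[p, ] - ctr)^2) < r2 - 1e-12) { inside <- TRUE; break }
    }
    if (!inside)
      edges <- rbind(edges, t(utils::combn(sort(tri), 2)))
  }
  unique(edges)
}

# Kruskal stress-1 of a configuration against dissimilarities, using
# isotonic regression on the rank-ordered dissimilarities.
stress1_oracle <- function(d, pts) {
  dd <- as.vector(stats::as.dist(d))
  conf <- as.vector(stats::dist(pts))
  o <- order(dd)
  iso <- stats::isoreg(conf[o])
  dhat <- iso$yf
  sqrt(sum((conf[o] - dhat)^2) / sum(conf^2))
}

# exact one-tailed Mantel p by enumerating all label permutations (n <= 6)
mantel_exact_p <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  n <- nrow(a)
  perm_list <- list()
  rec <- function(cur, rest) {
    if (!length(rest)) { perm_list[[length(perm_list) + 1]] <<- cur; return() }
    for (r in rest) rec(c(cur, r), setdiff(rest, r))
  }
  rec(integer(0), seq_len(n))
  r_of <- function(bb) stats::cor(a[lower.tri(a)], bb[lower.tri(bb)])
  r_obs <- r_of(b)
  r_all <- vapply(perm_list, function(p) r_of(b[p, p]), numeric(1))
  mean(r_all >= r_obs - 1e-12)
}

# random unrooted additive tree and its exact leaf distance matrix
random_additive_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.5, 2)
  list(tree = tr, d = ape::cophenetic.phylo(tr))
}
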