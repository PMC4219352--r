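# Shared fixtures for the structure/clustering tests.

# two spatially separated demes, strongly differentiated, with several
# individuals per site
make_deme_fixture <- function(n_sites = 6, per_site = 3, seed = 1) {
  set.seed(seed)
  half <- n_sites / 2
  site_id <- sprintf("S%02d", seq_len(n_sites))
  lon <- c(stats::runif(half, 0, 2), stats::runif(n_sites - half, 8, 10))
  lat <- stats::runif(n_sites, 40, 43)
  deme <- rep(1:2, c(half, n_sites - half))
  ids <- sprintf("i%03d", seq_len(n_sites * per_site))
  base <- c(paste(rep("A", 30), collapse = ""),
            paste(c(rep("T", 10), rep("A", 20)), collapse = ""))
  seqs <- character(0); site_of <- character(0)
  for (s in seq_len(n_sites)) for (r in seq_len(per_site)) {
    x <- strsplit(base[deme[s]], "")[[1]]
    flip <- sample(20:30, 1)
    x[flip] <- sample(setdiff(c("A", "C", "G", "T"), x[flip]), 1)
    seqs <- c(seqs, paste(x, collapse = ""))
    site_of <- c(site_of, site_id[s])
  }
  aln <- seq_alignment(seqs, ids, "l")
  list(d2 = pairwise_mismatch_matrix(aln),
       site_map = stats::setNames(site_of, ids),
       site_coords = data.frame(site_id = site_id, lon = lon, lat = lat),
       deme = stats::setNames(deme, site_id))
}

# exhaustive best Phi_CT over all K-group partitions (optionally contiguous
# under the same Delaunay adjacency the implementation uses)
exhaustive_best_phi <- function(fx, K, contiguous = TRUE) {
  sites <- fx$site_coords$site_id
  S <- length(sites)
  adj <- NULL
  if (contiguous) {
    net <- build_connectivity(fx$site_coords)
    adj <- lapply(stats::setNames(sites, sites), function(s)
      c(net$edges$to[net$edges$from == s], net$edges$from[net$edges$to == s]))
  }
  connected <- function(members) {
    if (!contiguous || length(members) <= 1) return(TRUE)
    seen <- members[1]; frontier <- members[1]
    while (length(frontier)) {
      nxt <- setdiff(intersect(unlist(adj[frontier]), members), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    length(seen) == length(members)
  }
  best <- -Inf
  grid <- do.call(expand.grid, rep(list(seq_len(K)), S))
  for (r in seq_len(nrow(grid))) {
    g <- as.integer(grid[r, ])
    if (length(unique(g)) != K) next
    ok <- all(vapply(unique(g), function(gg) connected(sites[g == gg]), logical(1)))
    if (!ok) next
    res <- amova_two_level(fx$d2, fx$site_map,
                           stats::setNames(paste0("G", g), sites), n_perm = 0)
    if (res$phi_ct > best) best <- res$phi_ct
  }
  best
}
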