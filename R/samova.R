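# Site-level evaluation machinery for SAMOVA: with sites as populations,
# all SSD terms reduce to block sums of the squared-distance matrix, so a
# candidate partition is scored in O(S^2) independent of sample size.

samova_precompute <- function(d2, site_of_ind) {
  sites <- sort(unique(site_of_ind))
  S <- length(sites)
  ind <- outer(site_of_ind, sites, "==") * 1          # N x S indicator
  W <- t(ind) %*% d2 %*% ind                          # site-block sums
  dimnames(W) <- list(sites, sites)
  ns <- colSums(ind)
  names(ns) <- sites
  N <- length(site_of_ind)
  list(W = W, ns = ns, N = N, sites = sites,
       ssd_t = sum(W) / (2 * N),
       ssd_wp = sum(diag(W) / (2 * ns)))
}

# Phi statistics for a site partition (integer group per site).
samova_phi <- function(pre, grp) {
  S <- length(pre$sites)
  G <- length(unique(grp))
  N <- pre$N; ns <- pre$ns
  ssd_wg <- sum(vapply(unique(grp), function(g) {
    ix <- which(grp == g)
    sum(pre$W[ix, ix]) / (2 * sum(ns[ix]))
  }, numeric(1)))
  ssd_ag <- pre$ssd_t - ssd_wg
  ssd_apwg <- ssd_wg - pre$ssd_wp
  df_ag <- G - 1; df_apwg <- S - G; df_wp <- N - S
  sigma_c <- if (df_wp > 0) pre$ssd_wp / df_wp else 0
  ng <- vapply(unique(grp), function(g) sum(ns[grp == g]), numeric(1))
  sum_np2_by_g <- vapply(unique(grp), function(g)
    sum(ns[grp == g]^2) / sum(ns[grp == g]), numeric(1))
  sigma_b <- if (df_apwg > 0)
    (ssd_apwg / df_apwg - sigma_c) / ((N - sum(sum_np2_by_g)) / df_apwg) else 0
  nprime <- (sum(sum_np2_by_g) - sum(ns^2) / N) / df_ag
  ndblp <- (N - sum(ng^2) / N) / df_ag
  sigma_a <- (ssd_ag / df_ag - sigma_c - nprime * sigma_b) / ndblp
  tot <- sigma_a + sigma_b + sigma_c
  c(phi_ct = if (abs(tot) < 1e-15) 0 else sigma_a / tot,
    phi_sc = if (abs(sigma_b + sigma_c) < 1e-15) 0 else sigma_b / (sigma_b + sigma_c),
    phi_st = if (abs(tot) < 1e-15) 0 else (sigma_a + sigma_b) / tot)
}

# adjacency list from a connectivity network (or complete graph)
site_adjacency <- function(sites, net = NULL) {
  adj <- stats::setNames(vector("list", length(sites)), sites)
  if (is.null(net)) {
    for (s in sites) adj[[s]] <- setdiff(sites, s)
  } else {
    for (k in seq_len(nrow(net$edges))) {
      a <- net$edges$from[k]; b <- net$edges$to[k]
      if (a %in% sites && b %in% sites) {
        adj[[a]] <- union(adj[[a]], b)
        adj[[b]] <- union(adj[[b]], a)
      }
    }
  }
  adj
}

# is the site set `members` connected under adjacency `adj`?
connected_set <- function(members, adj) {
  if (length(members) <= 1) return(TRUE)
  seen <- members[1]
  frontier <- members[1]
  while (length(frontier)) {
    nxt <- setdiff(intersect(unlist(adj[frontier]), members), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == length(members)
}

# random contiguous K-partition by region growing from K seed sites
grow_partition <- function(sites, adj, K) {
  grp <- stats::setNames(rep(NA_integer_, length(sites)), sites)
  seeds <- sample(sites, K)
  grp[seeds] <- seq_len(K)
  while (anyNA(grp)) {
    frontier <- names(grp)[!is.na(grp)]
    cand <- NULL
    for (s in sample(frontier)) {
      free <- setdiff(adj[[s]], names(grp)[!is.na(grp)])
      if (length(free)) { cand <- c(sample(free, 1), grp[[s]]); break }
    }
    if (is.null(cand)) { # disconnected contiguity graph: assign rest arbitrarily
      rest <- names(grp)[is.na(grp)]
      grp[rest] <- sample(K, length(rest), replace = TRUE)
      break
    }
    grp[cand[1]] <- as.integer(cand[2])
  }
  grp
}

#' Spatial AMOVA (SAMOVA): contiguity-constrained clustering of sites
#'
#' Searches for the partition of sampling sites into \code{K}
#' geographically contiguous groups that maximises the among-group
#' fixation index \eqn{\Phi_{CT}} (sites act as populations). Contiguity
#' is defined on the Delaunay triangulation of the site coordinates. The
#' search is simulated annealing over single-site reassignments to
#' adjacent groups: the initial temperature is set from a pilot sample of
#' moves so that roughly 80% of them would be accepted, with geometric
#' cooling to 1e-3 of that over \code{n_steps}; the best of \code{n_reps}
#' independent repetitions is returned.
#'
#' @param dm [dist_matrix] of squared inter-individual distances.
#' @param site_coords data.frame \code{site_id}, \code{lon}, \code{lat}.
#' @param sample_site_map named vector sample id -> site id.
#' @param K number of groups (2 <= K <= number of sites).
#' @param n_reps independent annealing repetitions.
#' @param n_steps annealing steps per repetition.
#' @param seed RNG seed.
#' @param contiguity enforce group contiguity under the Delaunay graph?
#' @return Object of class \code{samova_partition}: \code{K},
#'   \code{assignment} (named integer: site -> group), \code{phi}
#'   (phi_ct/phi_sc/phi_st attained) and \code{trace} metadata.
#' @export
samova <- function(dm, site_coords, sample_site_map, K, n_reps = 10,
                   n_steps = 10000, seed = 1, contiguity = TRUE) {
  d2 <- as.matrix(dm)
  site_of_ind <- as.character(sample_site_map[rownames(d2)])
  if (anyNA(site_of_ind)) stop("site missing for some samples", call. = FALSE)
  pre <- samova_precompute(d2, site_of_ind)
  sites <- pre$sites
  S <- length(sites)
  if (K > S) stop("K exceeds the number of sites", call. = FALSE)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  set.seed(seed)
  if (K == S) {
    grp <- stats::setNames(seq_len(S), sites)
    return(structure(list(K = K, assignment = grp, phi = samova_phi(pre, grp),
                          trace = list(n_reps = 0, n_steps = 0, seed = seed)),
                     class = "samova_partition"))
  }
  net <- if (contiguity && S >= 3) {
    sc <- site_coords[match(sites, site_coords$site_id), ]
    build_connectivity(sc)
  } else NULL
  adj <- site_adjacency(sites, net)
  propose <- function(grp) {
    # random contiguity-preserving single-site reassignment
    for (try in 1:50) {
      s <- sample(sites, 1)
      g <- grp[[s]]
      if (sum(grp == g) <= 1) next
      nbr_groups <- setdiff(unique(grp[adj[[s]]]), g)
      if (!length(nbr_groups)) next
      g2 <- if (length(nbr_groups) == 1) nbr_groups else sample(nbr_groups, 1)
      if (contiguity) {
        rest <- setdiff(names(grp)[grp == g], s)
        if (!connected_set(rest, adj)) next
      }
      new <- grp; new[[s]] <- g2
      return(new)
    }
    NULL
  }
  best_grp <- NULL; best_phi <- -Inf
  for (rep in seq_len(n_reps)) {
    grp <- grow_partition(sites, adj, K)
    cur <- samova_phi(pre, grp)[["phi_ct"]]
    # pilot moves to set the initial temperature (~80% acceptance)
    deltas <- c()
    for (i in 1:30) {
      cand <- propose(grp)
      if (!is.null(cand))
        deltas <- c(deltas, abs(samova_phi(pre, cand)[["phi_ct"]] - cur))
    }
    t0 <- max(mean(deltas[deltas > 0], na.rm = TRUE), 1e-6)
    if (!is.finite(t0)) t0 <- 1e-3
    t0 <- t0 / (-log(0.8))
    cool <- (1e-3)^(1 / n_steps)
    temp <- t0
    if (cur > best_phi) { best_phi <- cur; best_grp <- grp }
    for (step in seq_len(n_steps)) {
      cand <- propose(grp)
      temp <- temp * cool
      if (is.null(cand)) next
      phi_new <- samova_phi(pre, cand)[["phi_ct"]]
      if (phi_new >= cur || stats::runif(1) < exp((phi_new - cur) / temp)) {
        grp <- cand; cur <- phi_new
        if (cur > best_phi) { best_phi <- cur; best_grp <- grp }
      }
    }
  }
  # canonical group numbering by first site occurrence
  relab <- match(best_grp, unique(best_grp))
  names(relab) <- names(best_grp)
  structure(list(K = K, assignment = relab, phi = samova_phi(pre, relab),
                 trace = list(n_reps = n_reps, n_steps = n_steps, seed = seed)),
            class = "samova_partition")
}

#' @export
print.samova_partition <- function(x, ...) {
  cat(sprintf("SAMOVA: K = %d, Phi_CT = %.2f (Phi_ST = %.2f, Phi_SC = %.2f)\n",
              x$K, x$phi[["phi_ct"]], x$phi[["phi_st"]], x$phi[["phi_sc"]]))
  invisible(x)
}

#' Scan SAMOVA over a range of K
#'
#' Runs [samova] for each K and tabulates the attained Phi statistics,
#' flagging values of K whose best partition contains single-site groups
#' (a sign that added groups have stopped being biologically meaningful —
#' reported as a flag, never auto-decided).
#'
#' @inheritParams samova
#' @param K_range integer vector of K values.
#' @return data.frame (K, phi_ct, phi_sc, phi_st, singleton_groups) of
#'   class \code{samova_scan}, with the partitions in attribute
#'   \code{partitions}.
#' @export
samova_scan <- function(dm, site_coords, sample_site_map, K_range = 2:10,
                        n_reps = 10, n_steps = 10000, seed = 1,
                        contiguity = TRUE) {
  parts <- lapply(K_range, function(K)
    samova(dm, site_coords, sample_site_map, K, n_reps = n_reps,
           n_steps = n_steps, seed = seed + K, contiguity = contiguity))
  tab <- data.frame(
    K = K_range,
    phi_ct = vapply(parts, function(p) p$phi[["phi_ct"]], numeric(1)),
    phi_sc = vapply(parts, function(p) p$phi[["phi_sc"]], numeric(1)),
    phi_st = vapply(parts, function(p) p$phi[["phi_st"]], numeric(1)),
    singleton_groups = vapply(parts, function(p)
      sum(table(p$assignment) == 1), integer(1)))
  if (any(tab$singleton_groups > 0))
    message("single-site groups appear at K = ",
            paste(tab$K[tab$singleton_groups > 0], collapse = ", "))
  attr(tab, "partitions") <- parts
  class(tab) <- c("samova_scan", class(tab))
  tab
}
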