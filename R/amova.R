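# Core AMOVA sums-of-squared-deviations decomposition.
#
# `d2` is the matrix of squared inter-individual molecular distances
# (for sequences: pairwise mismatch counts, unscaled — the Arlequin
# convention). SSD(total) = sum(d2)/2N; within a set S,
# SSD(S) = sum(d2[S,S])/(2|S|).
amova_decompose <- function(d2, pops, groups = NULL) {
  pops <- as.character(pops)
  N <- nrow(d2)
  np <- table(pops)
  P <- length(np)
  ssd_t <- sum(d2) / (2 * N)
  ssd_wp <- sum(vapply(names(np), function(p) {
    ix <- which(pops == p)
    sum(d2[ix, ix]) / (2 * length(ix))
  }, numeric(1)))
  if (is.null(groups)) {
    # one-level design: among populations / within populations
    ssd_ap <- ssd_t - ssd_wp
    df_ap <- P - 1; df_wp <- N - P
    sigma_w <- if (df_wp > 0) ssd_wp / df_wp else 0
    nprime <- (N - sum(np^2) / N) / (P - 1)
    sigma_a <- (ssd_ap / df_ap - sigma_w) / nprime
    tot <- sigma_a + sigma_w
    phi_st <- if (abs(tot) < 1e-15) 0 else sigma_a / tot
    return(list(sigma = c(among = sigma_a, within = sigma_w),
                ssd = c(total = ssd_t, among = ssd_ap, within = ssd_wp),
                df = c(among = df_ap, within = df_wp),
                phi_st = phi_st))
  }
  grp_of_ind <- groups[pops]
  if (anyNA(grp_of_ind)) stop("population(s) without a group", call. = FALSE)
  ng <- table(grp_of_ind)
  G <- length(ng)
  if (any(ng == 0)) stop("empty group", call. = FALSE)
  ssd_wg <- sum(vapply(names(ng), function(g) {
    ix <- which(grp_of_ind == g)
    sum(d2[ix, ix]) / (2 * length(ix))
  }, numeric(1)))
  ssd_ag <- ssd_t - ssd_wg
  ssd_apwg <- ssd_wg - ssd_wp
  df_ag <- G - 1; df_apwg <- P - G; df_wp <- N - P
  sigma_c <- if (df_wp > 0) ssd_wp / df_wp else 0
  # Excoffier n-coefficients for unbalanced designs
  sum_np2_by_g <- vapply(names(ng), function(g) {
    sum(np[unique(pops[grp_of_ind == g])]^2) / ng[[g]]
  }, numeric(1))
  if (df_apwg > 0) {
    n_co <- (N - sum(sum_np2_by_g)) / df_apwg
    sigma_b <- (ssd_apwg / df_apwg - sigma_c) / n_co
  } else sigma_b <- 0
  nprime <- (sum(sum_np2_by_g) - sum(np^2) / N) / df_ag
  ndblp <- (N - sum(ng^2) / N) / df_ag
  sigma_a <- (ssd_ag / df_ag - sigma_c - nprime * sigma_b) / ndblp
  tot <- sigma_a + sigma_b + sigma_c
  zero <- abs(tot) < 1e-15
  list(sigma = c(among_groups = sigma_a, among_pops_within = sigma_b,
                 within_pops = sigma_c),
       ssd = c(total = ssd_t, among_groups = ssd_ag,
               among_pops_within = ssd_apwg, within_pops = ssd_wp),
       df = c(among_groups = df_ag, among_pops_within = df_apwg,
              within_pops = df_wp),
       phi_ct = if (zero) 0 else sigma_a / tot,
       phi_sc = if (abs(sigma_b + sigma_c) < 1e-15) 0 else sigma_b / (sigma_b + sigma_c),
       phi_st = if (zero) 0 else (sigma_a + sigma_b) / tot)
}

#' Global Phi_ST (one-level AMOVA) with permutation test
#'
#' Partitions squared molecular distances into among- and within-population
#' components and reports the fixation index
#' \eqn{\Phi_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)}. Significance
#' is assessed by shuffling individuals among populations; the p-value uses
#' the (hits + 1)/(N + 1) correction. Variance components can be negative
#' and are not clamped.
#'
#' @param dm [dist_matrix] of squared inter-individual distances (for
#'   sequences: mismatch counts, see [pairwise_mismatch_matrix]).
#' @param populations named character vector (sample id -> population) or
#'   unnamed vector aligned with \code{rownames(dm)}.
#' @param n_perm number of permutations (0 = no test).
#' @param seed RNG seed for the permutations.
#' @return Object of class \code{amova}, with elements \code{phi_st},
#'   \code{p_value}, \code{sigma}, \code{ssd}, \code{df},
#'   \code{n_permutations}.
#' @export
global_phi_st <- function(dm, populations, n_perm = 10000, seed = 1) {
  d2 <- as.matrix(dm)
  pops <- resolve_labels(populations, rownames(d2))
  if (length(unique(pops)) < 2)
    stop("global Phi_ST undefined for a single population", call. = FALSE)
  obs <- amova_decompose(d2, pops)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    hits <- 0L
    for (r in seq_len(n_perm)) {
      perm <- sample(pops)
      if (amova_decompose(d2, perm)$phi_st >= obs$phi_st - 1e-12) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
  }
  structure(c(obs, list(p_value = p, n_permutations = n_perm, design = "one-level")),
            class = "amova")
}

#' Two-level (hierarchical) AMOVA
#'
#' Decomposes squared molecular distances into among-group,
#' among-population-within-group and within-population components via the
#' standard unbalanced-design coefficients, reporting
#' \eqn{\Phi_{CT}, \Phi_{SC}, \Phi_{ST}}. Three permutation schemes are
#' run: individuals among populations within groups (\eqn{\Phi_{SC}}),
#' whole populations among groups (\eqn{\Phi_{CT}}), and individuals among
#' populations among groups (\eqn{\Phi_{ST}}).
#'
#' @inheritParams global_phi_st
#' @param groups named character vector: population -> group.
#' @return Object of class \code{amova} with \code{sigma}, \code{phi_ct},
#'   \code{phi_sc}, \code{phi_st} and permutation p-values \code{p_ct},
#'   \code{p_sc}, \code{p_st}.
#' @export
amova_two_level <- function(dm, populations, groups, n_perm = 10000, seed = 1) {
  d2 <- as.matrix(dm)
  pops <- resolve_labels(populations, rownames(d2))
  if (is.null(names(groups))) stop("groups must be named by population", call. = FALSE)
  groups <- vapply(groups, as.character, character(1))
  if (!all(unique(pops) %in% names(groups)))
    stop("population(s) without a group: ",
         paste(setdiff(unique(pops), names(groups)), collapse = ", "), call. = FALSE)
  if (length(unique(groups[unique(pops)])) < 2)
    stop("need >= 2 groups", call. = FALSE)
  obs <- amova_decompose(d2, pops, groups)
  p_ct <- p_sc <- p_st <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    grp_of_ind <- groups[pops]
    hits_ct <- hits_sc <- hits_st <- 0L
    upop <- unique(pops)
    for (r in seq_len(n_perm)) {
      # Phi_SC: individuals shuffled among populations within their group
      perm_sc <- pops
      for (g in unique(grp_of_ind)) {
        ix <- which(grp_of_ind == g)
        perm_sc[ix] <- sample(pops[ix])
      }
      if (amova_decompose(d2, perm_sc, groups)$phi_sc >= obs$phi_sc - 1e-12)
        hits_sc <- hits_sc + 1L
      # Phi_CT: whole populations reassigned among groups
      perm_groups <- stats::setNames(sample(groups[upop]), upop)
      if (amova_decompose(d2, pops, perm_groups)$phi_ct >= obs$phi_ct - 1e-12)
        hits_ct <- hits_ct + 1L
      # Phi_ST: individuals shuffled freely among populations among groups
      if (amova_decompose(d2, sample(pops), groups)$phi_st >= obs$phi_st - 1e-12)
        hits_st <- hits_st + 1L
    }
    p_ct <- (hits_ct + 1) / (n_perm + 1)
    p_sc <- (hits_sc + 1) / (n_perm + 1)
    p_st <- (hits_st + 1) / (n_perm + 1)
  }
  structure(c(obs, list(p_ct = p_ct, p_sc = p_sc, p_st = p_st,
                        n_permutations = n_perm, design = "two-level")),
            class = "amova")
}

#' @export
print.amova <- function(x, ...) {
  cat("AMOVA (", x$design, ")\n", sep = "")
  tab <- data.frame(df = x$df, SSD = round(x$ssd[names(x$df)], 4),
                    sigma2 = round(x$sigma, 4))
  print(tab)
  if (x$design == "one-level") {
    cat(sprintf("Phi_ST = %.2f", x$phi_st))
    if (!is.na(x$p_value)) cat(sprintf("  (p = %.4g, %d permutations)",
                                       x$p_value, x$n_permutations))
  } else {
    cat(sprintf("Phi_CT = %.2f  Phi_SC = %.2f  Phi_ST = %.2f",
                x$phi_ct, x$phi_sc, x$phi_st))
    if (!is.na(x$p_ct)) cat(sprintf("\np(CT) = %.4g  p(SC) = %.4g  p(ST) = %.4g",
                                    x$p_ct, x$p_sc, x$p_st))
  }
  cat("\n")
  invisible(x)
}

# Resolve a population/group labelling against matrix labels: accepts a
# named vector (matched by name) or an unnamed vector in matrix order.
resolve_labels <- function(labels, ids) {
  if (!is.null(names(labels))) {
    out <- as.character(labels[ids])
    if (anyNA(out)) stop("labels missing for: ",
                         paste(ids[is.na(out)], collapse = ", "), call. = FALSE)
  } else {
    if (length(labels) != length(ids))
      stop("label vector length does not match matrix", call. = FALSE)
    out <- as.character(labels)
  }
  out
}
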