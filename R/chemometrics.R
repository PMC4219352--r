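#' Discard trace compounds
#'
#' A compound is kept iff its relative amount reaches \code{threshold}
#' (default 0.1%) in at least one sample (boundary inclusive). Rows are
#' deliberately not renormalised afterwards: the removed mass is trace
#' (< 0.1% per compound) and renormalisation would distort the retained
#' relative amounts.
#'
#' @param chem a [chem_profile] matrix (relative amounts, %).
#' @param threshold minimum relative amount (%) a compound must reach.
#' @return Filtered [chem_profile].
#' @export
filter_compounds <- function(chem, threshold = 0.1) {
  keep <- apply(chem, 2, max) >= threshold
  if (!any(keep)) stop("all compounds below threshold", call. = FALSE)
  out <- chem[, keep, drop = FALSE]
  structure(out, class = class(chem), flagged = attr(chem, "flagged"))
}

#' Log-transform and standardize a compositional matrix
#'
#' Each cell is transformed as \eqn{y = \log_{10}(x + 1)} (damping the
#' orders-of-magnitude spread between major and trace compounds), then each
#' compound column is centred and scaled to mean 0, sd 1 (sample sd).
#' Zero-variance compounds are set to all-zeros with a warning.
#'
#' @param chem [chem_profile] or non-negative numeric matrix.
#' @return Plain numeric matrix (samples x compounds), attribute
#'   \code{zero_variance} naming constant compounds.
#' @export
transform_standardize <- function(chem) {
  m <- unclass(as.matrix(chem))
  if (any(m < 0)) stop("negative input", call. = FALSE)
  y <- log10(m + 1)
  sds <- apply(y, 2, stats::sd)
  zv <- colnames(y)[sds < 1e-15]
  if (length(zv)) warning("zero-variance compound(s) set to 0: ",
                          paste(zv, collapse = ", "))
  out <- scale(y)
  out[, sds < 1e-15] <- 0
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  attr(out, "zero_variance") <- zv
  out
}

#' Bray-Curtis distance matrix
#'
#' \eqn{BC_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})}.
#' Bray-Curtis requires non-negative data, but the transformed-standardized
#' chemical matrix contains negatives; with \code{shift = TRUE} (the
#' default used for the standardized route) the matrix is first shifted by
#' its global minimum. Set \code{shift = FALSE} when passing raw relative
#' amounts.
#'
#' @param m numeric matrix (samples x features).
#' @param shift shift the matrix by its global minimum before computing?
#' @return [dist_matrix] in \[0, 1\].
#' @export
bray_curtis <- function(m, shift = any(m < 0)) {
  m <- as.matrix(m)
  if (shift) m <- m - min(m)
  if (any(m < 0)) stop("negative values: use shift = TRUE", call. = FALSE)
  zero <- rowSums(m) == 0
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  if (any(zero)) {
    warning("sample pair(s) with zero total abundance: distance set to 0")
    d[zero, zero] <- 0          # only both-zero pairs are undefined (0/0)
    d[!is.finite(d)] <- 0
  }
  if (is.null(rownames(d))) dimnames(d) <- list(rownames(m), rownames(m))
  dist_matrix(d)
}

#' Non-metric multidimensional scaling with random restarts
#'
#' Kruskal stress-1 nMDS (isotonic regression, via \code{vegan::monoMDS});
#' run 1 starts from the metric (PCoA) configuration, the remaining runs
#' from random configurations, and the lowest-stress solution is returned.
#'
#' @param dm [dist_matrix] (dissimilarities).
#' @param k number of dimensions (default 3).
#' @param n_runs number of starts (default 50).
#' @param seed RNG seed.
#' @return Object of class \code{chem_nmds}: \code{points} (n x k),
#'   \code{stress} (stress-1, in \[0,1\]), \code{k}, \code{n_runs},
#'   \code{best_run}.
#' @export
chem_nmds <- function(dm, k = 3, n_runs = 50, seed = 1) {
  d <- stats::as.dist(as.matrix(dm))
  n <- attr(d, "Size")
  if (k >= n - 1) stop("k must be < n - 1", call. = FALSE)
  if (n < k + 2) stop("need at least k + 2 samples", call. = FALSE)
  set.seed(seed)
  best <- NULL; best_run <- NA_integer_
  for (r in seq_len(n_runs)) {
    y <- if (r == 1) {
      suppressWarnings(stats::cmdscale(d, k = k))
    } else {
      matrix(stats::runif(n * k, -1, 1), n, k)
    }
    if (ncol(y) < k) y <- cbind(y, matrix(stats::runif(n * (k - ncol(y)), -1e-4, 1e-4), n))
    fit <- vegan::monoMDS(d, y = y, k = k, model = "global")
    if (is.null(best) || fit$stress < best$stress) { best <- fit; best_run <- r }
  }
  structure(list(points = best$points, stress = best$stress, k = k,
                 n_runs = n_runs, best_run = best_run),
            class = "chem_nmds")
}

#' @export
print.chem_nmds <- function(x, ...) {
  cat(sprintf("nMDS: k = %d, best of %d runs (run %d), stress-1 = %.4f\n",
              x$k, x$n_runs, x$best_run, x$stress))
  invisible(x)
}

#' Permutational MANOVA (perMANOVA) on a distance matrix
#'
#' Pseudo-F from the Gower-centred decomposition of the distance matrix
#' (via \code{vegan::adonis2}), p-value by free permutation of sample
#' labels. With more than two groups, all pairwise tests are run and
#' Bonferroni-adjusted.
#'
#' @param dm [dist_matrix].
#' @param groups group labels (named by sample id, or in matrix order).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return Object of class \code{permanova}: \code{f}, \code{p},
#'   \code{df_between}, \code{df_within}, \code{n_permutations},
#'   \code{pairwise} (NULL for 2 groups).
#' @export
permanova <- function(dm, groups, n_perm = 10000, seed = 1) {
  d <- as.matrix(dm)
  g <- factor(resolve_labels(groups, rownames(d)))
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(g) < 2)) stop("every group needs n >= 2", call. = FALSE)
  set.seed(seed)
  fit <- vegan::adonis2(stats::as.dist(d) ~ g,
                        data = data.frame(g = g), permutations = n_perm)
  res <- list(f = fit$F[1], p = fit$`Pr(>F)`[1],
              df_between = fit$Df[1], df_within = fit$Df[2],
              n_permutations = n_perm, pairwise = NULL)
  if (nlevels(g) > 2) {
    prs <- utils::combn(levels(g), 2)
    pw <- lapply(seq_len(ncol(prs)), function(j) {
      sel <- g %in% prs[, j]
      sub <- d[sel, sel]
      gs <- droplevels(g[sel])
      f2 <- vegan::adonis2(stats::as.dist(sub) ~ gs,
                           data = data.frame(gs = gs), permutations = n_perm)
      data.frame(group1 = prs[1, j], group2 = prs[2, j],
                 f = f2$F[1], p = f2$`Pr(>F)`[1])
    })
    pw <- do.call(rbind, pw)
    pw$p_adj <- stats::p.adjust(pw$p, method = "bonferroni")
    res$pairwise <- pw
  }
  structure(res, class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("perMANOVA: F = %.4g (df = %d, %d), p = %.4g (%d permutations)\n",
              x$f, x$df_between, x$df_within, x$p, x$n_permutations))
  if (!is.null(x$pairwise)) {
    cat("pairwise (Bonferroni-adjusted):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

# Pseudo-Euclidean principal-coordinate embedding of a distance matrix:
# coordinates X and axis signs s such that sum_k s_k (X_ik - X_jk)^2
# reproduces d_ij^2 exactly (negative eigenvalues kept with sign -1).
pcoa_embed <- function(d) {
  n <- nrow(d)
  J <- diag(n) - 1 / n
  G <- -0.5 * J %*% (d^2) %*% J
  ee <- eigen((G + t(G)) / 2, symmetric = TRUE)
  keep <- abs(ee$values) > max(abs(ee$values)) * 1e-10
  list(X = ee$vectors[, keep, drop = FALSE] %*%
         diag(sqrt(abs(ee$values[keep])), sum(keep)),
       sign = sign(ee$values[keep]))
}

# distance of each sample to its group centroid in the embedding
centroid_distances <- function(emb, g) {
  z <- numeric(nrow(emb$X))
  for (lv in levels(g)) {
    ix <- which(g == lv)
    cen <- colMeans(emb$X[ix, , drop = FALSE])
    d2 <- sweep(emb$X[ix, , drop = FALSE], 2, cen)^2 %*% emb$sign
    z[ix] <- sqrt(pmax(0, d2))
  }
  z
}

one_way_f <- function(z, g) {
  k <- nlevels(g); n <- length(z)
  m <- tapply(z, g, mean)
  ssb <- sum(tabulate(g) * (m - mean(z))^2)
  ssw <- sum((z - m[g])^2)
  (ssb / (k - 1)) / (ssw / (n - k))
}

#' Multivariate homogeneity of group dispersions
#'
#' Distances from each sample to its group centroid are computed in the
#' principal-coordinate embedding of the distance matrix, with
#' negative-eigenvalue axes retained (their squared contributions
#' subtracted), so the observed distances match
#' \code{vegan::betadisper(..., type = "centroid")} exactly. Groups are
#' compared by the one-way ANOVA F on those distances plus a permutation
#' p-value in which group labels are permuted and the centroids and
#' distances re-estimated under each permutation — re-estimation keeps the
#' test exact for small groups, where permuting the fixed observed
#' distances is anticonservative. The per-group mean distance-to-centroid
#' is the "variability" statistic interpolated on the landscape maps.
#'
#' @param dm [dist_matrix].
#' @param groups group labels.
#' @param n_perm permutations for the dispersion test.
#' @param seed RNG seed.
#' @return Object of class \code{dispersion_test}: \code{distances}
#'   (per-sample), \code{variability} (per-group mean),
#'   \code{f}, \code{p_anova}, \code{p_perm}.
#' @export
dispersion_test <- function(dm, groups, n_perm = 999, seed = 1) {
  d <- as.matrix(dm)
  g <- factor(resolve_labels(groups, rownames(d)))
  if (all(abs(d) < 1e-12)) {
    message("all samples identical: variability 0, test skipped")
    dists <- stats::setNames(rep(0, nrow(d)), rownames(d))
    return(structure(list(distances = dists, variability = tapply(dists, g, mean),
                          f = NA_real_, p_anova = NA_real_, p_perm = NA_real_),
                     class = "dispersion_test"))
  }
  emb <- pcoa_embed(d)
  dists <- stats::setNames(centroid_distances(emb, g), rownames(d))
  variability <- tapply(dists, g, mean)
  if (nlevels(g) < 2) {
    message("single group: distances reported, dispersion test skipped")
    return(structure(list(distances = dists, variability = variability,
                          f = NA_real_, p_anova = NA_real_, p_perm = NA_real_),
                     class = "dispersion_test"))
  }
  f_obs <- one_way_f(dists, g)
  n <- nrow(d); k <- nlevels(g)
  p_anova <- stats::pf(f_obs, k - 1, n - k, lower.tail = FALSE)
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(n_perm)) {
    gp <- factor(sample(as.character(g)), levels = levels(g))
    if (one_way_f(centroid_distances(emb, gp), gp) >= f_obs - 1e-12)
      hits <- hits + 1L
  }
  structure(list(distances = dists, variability = variability,
                 f = f_obs, p_anova = p_anova,
                 p_perm = (hits + 1) / (n_perm + 1), n_permutations = n_perm),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  cat("Multivariate dispersion: F =", format(x$f, digits = 4),
      " p(ANOVA) =", format(x$p_anova, digits = 3),
      " p(perm) =", format(x$p_perm, digits = 3), "\n")
  cat("per-group variability (mean distance to centroid):\n")
  print(round(x$variability, 4))
  invisible(x)
}

#' Indicator-value (IndVal) analysis of compounds
#'
#' For compound \eqn{c} and group \eqn{g}:
#' \eqn{IndVal_{gc} = A_{gc} \times B_{gc} \times 100}, where
#' \eqn{A_{gc}} (specificity) is the mean abundance of \eqn{c} in \eqn{g}
#' divided by the sum of its group-mean abundances, and \eqn{B_{gc}}
#' (fidelity) is the fraction of samples of \eqn{g} in which \eqn{c} is
#' present (> 0). Significance of a compound's maximum IndVal is assessed
#' by label randomization. Applied to untransformed relative amounts.
#'
#' @param m non-negative matrix (samples x compounds), e.g. a filtered
#'   [chem_profile].
#' @param groups group labels.
#' @param n_perm number of randomizations.
#' @param alpha significance level.
#' @param seed RNG seed.
#' @return Object of class \code{indval_result}: \code{indval} (group x
#'   compound matrix), \code{max_group}, \code{p} (per compound),
#'   \code{significant} (logical), \code{n_significant} (per group, among
#'   compounds whose best group is that group).
#' @export
indval <- function(m, groups, n_perm = 999, alpha = 0.05, seed = 1) {
  m <- unclass(as.matrix(m))
  if (any(m < 0)) stop("abundances must be non-negative", call. = FALSE)
  g <- factor(resolve_labels(groups, rownames(m)))
  if (nlevels(g) < 2) stop("need >= 2 groups", call. = FALSE)
  iv_fun <- function(gg) {
    means <- apply(m, 2, function(col) tapply(col, gg, mean))
    denom <- colSums(means)
    A <- sweep(means, 2, ifelse(denom > 0, denom, 1), "/")
    A[, denom == 0] <- 0
    B <- apply(m > 0, 2, function(col) tapply(col, gg, mean))
    A * B * 100
  }
  obs <- iv_fun(g)
  obs_max <- apply(obs, 2, max)
  set.seed(seed)
  exceed <- rep(0L, ncol(m))
  for (r in seq_len(n_perm)) {
    pm <- iv_fun(sample(g))
    exceed <- exceed + (apply(pm, 2, max) >= obs_max - 1e-12)
  }
  p <- (exceed + 1) / (n_perm + 1)
  max_group <- rownames(obs)[apply(obs, 2, which.max)]
  sig <- p <= alpha & obs_max > 0
  n_sig <- vapply(levels(g), function(lv) sum(sig & max_group == lv), integer(1))
  structure(list(indval = obs, max_group = stats::setNames(max_group, colnames(m)),
                 p = stats::setNames(p, colnames(m)),
                 significant = stats::setNames(sig, colnames(m)),
                 n_significant = n_sig, alpha = alpha, n_permutations = n_perm),
            class = "indval_result")
}

#' @export
print.indval_result <- function(x, ...) {
  cat("IndVal:", length(x$p), "compounds,",
      sum(x$significant), "significant at alpha =", x$alpha, "\n")
  cat("significant indicator compounds per group:\n")
  print(x$n_significant)
  invisible(x)
}
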