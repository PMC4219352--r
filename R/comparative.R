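#' Geographic distance matrix between samples
#'
#' Great-circle (haversine) distances in km on a 6371-km sphere.
#'
#' @param samples a sample table ([read_sample_table]).
#' @return [dist_matrix] labelled by sample id.
#' @export
geographic_distance_matrix <- function(samples) {
  haversine_km(samples$lon, samples$lat, samples$id)
}

#' Binary colour-pattern distance matrix
#'
#' Distance 0 when two individuals share the same colour pattern, 1
#' otherwise.
#'
#' @param samples a sample table.
#' @return [dist_matrix] with values in \{0, 1\}.
#' @export
colour_distance_matrix <- function(samples) {
  lab <- samples$colour_label
  if (any(is.na(lab) | !nzchar(lab)))
    stop("missing colour label for sample(s): ",
         paste(samples$id[is.na(lab) | !nzchar(lab)], collapse = ", "),
         call. = FALSE)
  d <- outer(lab, lab, "!=") * 1
  dimnames(d) <- list(samples$id, samples$id)
  dist_matrix(d)
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the off-diagonal entries; significance by
#' simultaneous row/column permutation of the second matrix (one-tailed
#' upper by default, testing positive association), with the
#' (hits + 1)/(N + 1) correction. Delegated to \code{vegan::mantel};
#' matrices are aligned on their common labels first.
#'
#' @param a,b [dist_matrix] objects sharing labels.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return Object of class \code{mantel_result}: \code{r}, \code{p},
#'   \code{n}, \code{n_permutations}, \code{one_tailed = TRUE}.
#' @export
mantel_test <- function(a, b, n_perm = 10000, seed = 1) {
  al <- align_dist(as.matrix(a), as.matrix(b))
  if (nrow(al$a) < 4) stop("need >= 4 common labels", call. = FALSE)
  check_nondegenerate(al$a, "first")
  check_nondegenerate(al$b, "second")
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(al$a), stats::as.dist(al$b),
                       method = "pearson", permutations = n_perm)
  structure(list(r = unname(fit$statistic), p = fit$signif, n = nrow(al$a),
                 n_permutations = n_perm, one_tailed = TRUE),
            class = "mantel_result")
}

#' Partial Mantel test
#'
#' Correlation of \code{a} and \code{b} controlling for \code{c}
#' (typically geographic distance):
#' \eqn{r_{AB\cdot C} = (r_{AB} - r_{AC} r_{BC}) /
#' \sqrt{(1 - r_{AC}^2)(1 - r_{BC}^2)}}, permutation p via
#' \code{vegan::mantel.partial}.
#'
#' @param a,b,c [dist_matrix] objects sharing labels.
#' @inheritParams mantel_test
#' @return A \code{mantel_result}.
#' @export
partial_mantel_test <- function(a, b, c, n_perm = 10000, seed = 1) {
  common <- Reduce(intersect, list(rownames(a), rownames(b), rownames(c)))
  if (length(common) < 4) stop("need >= 4 common labels", call. = FALSE)
  am <- as.matrix(a)[common, common]; bm <- as.matrix(b)[common, common]
  cm <- as.matrix(c)[common, common]
  check_nondegenerate(am, "first"); check_nondegenerate(bm, "second")
  check_nondegenerate(cm, "conditioning")
  rac <- stats::cor(am[lower.tri(am)], cm[lower.tri(cm)])
  rbc <- stats::cor(bm[lower.tri(bm)], cm[lower.tri(cm)])
  if (abs(rac) > 1 - 1e-12 || abs(rbc) > 1 - 1e-12)
    stop("conditioning matrix perfectly correlated with an input", call. = FALSE)
  set.seed(seed)
  fit <- vegan::mantel.partial(stats::as.dist(am), stats::as.dist(bm),
                               stats::as.dist(cm), method = "pearson",
                               permutations = n_perm)
  structure(list(r = unname(fit$statistic), p = fit$signif, n = length(common),
                 n_permutations = n_perm, one_tailed = TRUE),
            class = "mantel_result")
}

check_nondegenerate <- function(m, what) {
  if (stats::sd(m[lower.tri(m)]) < 1e-15)
    stop("Mantel r undefined: ", what, " matrix constant off-diagonal",
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel: r = %.3f, p = %.4g (n = %d, %d permutations, %s)\n",
              x$r, x$p, x$n, x$n_permutations,
              if (x$one_tailed) "one-tailed" else "two-tailed"))
  invisible(x)
}

#' The full Mantel battery
#'
#' Runs the six Mantel tests (genetic, chemical, colour vs geographic and
#' each other) and the three partial Mantel tests controlling for
#' geographic distance.
#'
#' @param genetic,chemical,colour,geographic [dist_matrix] objects.
#' @inheritParams mantel_test
#' @return data.frame: test, r, p, n, n_perm.
#' @export
mantel_battery <- function(genetic, chemical, colour, geographic,
                           n_perm = 10000, seed = 1) {
  runs <- list(
    genetic_vs_geographic = list(genetic, geographic),
    chemical_vs_geographic = list(chemical, geographic),
    colour_vs_geographic = list(colour, geographic),
    genetic_vs_chemical = list(genetic, chemical),
    genetic_vs_colour = list(genetic, colour),
    chemical_vs_colour = list(chemical, colour))
  out <- lapply(names(runs), function(nm) {
    r <- mantel_test(runs[[nm]][[1]], runs[[nm]][[2]], n_perm, seed)
    data.frame(test = nm, partial = FALSE, r = r$r, p = r$p, n = r$n)
  })
  pruns <- list(
    genetic_vs_chemical_given_geo = list(genetic, chemical),
    genetic_vs_colour_given_geo = list(genetic, colour),
    chemical_vs_colour_given_geo = list(chemical, colour))
  pout <- lapply(names(pruns), function(nm) {
    r <- partial_mantel_test(pruns[[nm]][[1]], pruns[[nm]][[2]], geographic,
                             n_perm, seed)
    data.frame(test = nm, partial = TRUE, r = r$r, p = r$p, n = r$n)
  })
  res <- do.call(rbind, c(out, pout))
  res$n_perm <- n_perm
  res
}

#' Regression of chemical variability on genetic diversity
#'
#' Gaussian identity-link linear model of per-group MMS variability (mean
#' distance to group centroid) on per-group nucleotide diversity (averaged
#' over loci). Groups with only one sample must be excluded upstream
#' (their diversity is undefined); groups with NA in either variable are
#' dropped here.
#'
#' @param group_diversity named numeric: geo_group -> mean pi.
#' @param group_variability named numeric: geo_group -> MMS variability.
#' @return list with \code{slope}, \code{p} (slope t-test), \code{n},
#'   \code{fit} (the glm object).
#' @export
diversity_variability_regression <- function(group_diversity, group_variability) {
  common <- intersect(names(group_diversity), names(group_variability))
  x <- group_diversity[common]; y <- group_variability[common]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 groups with both values", call. = FALSE)
  fit <- stats::glm(y ~ x, family = stats::gaussian())
  co <- summary(fit)$coefficients
  list(slope = co["x", "Estimate"], p = co["x", "Pr(>|t|)"],
       n = length(x), fit = fit)
}
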