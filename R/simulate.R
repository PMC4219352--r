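#' Configuration for the refugial-lineage simulator
#'
#' Defaults emulate the structure of the intended empirical setting: ~40
#' sampling sites over a European-scale bounding box, ~250 individuals,
#' four polymorphic loci with lineage-structured haplotypes descending
#' from K = 3 refugial lineages, compositional chemical profiles with a
#' lineage-specific qualitative compound switch plus multiplicative
#' noise, and colour labels partially concordant with lineage.
#'
#' @param n_sites number of sampling sites.
#' @param n_individuals total individuals (spread round-robin over sites).
#' @param K_lineages number of refugial lineages (>= 1).
#' @param loci data.frame with columns \code{locus_id}, \code{length}
#'   (bp), \code{mutation_scale} (expected private substitutions per
#'   individual along its star branch) and \code{divergence} (expected
#'   pairwise between-lineage substitutions).
#' @param bbox c(lon_min, lon_max, lat_min, lat_max).
#' @param refugia K x 2 matrix of refugium centroids (lon, lat); default
#'   centroids are spread over the box.
#' @param site_spread sd (degrees) of site scatter around its refugium.
#' @param contact_zone_width width (degrees) of the zone, around the
#'   equidistance line between two refugia, in which lineage membership
#'   mixes.
#' @param n_compounds number of chemical compounds.
#' @param n_switch qualitative-switch compounds per lineage (present only
#'   in that lineage).
#' @param chem_noise_sd sdlog of the multiplicative lognormal noise on
#'   compound amounts.
#' @param lineage_effect sdlog of the lineage-level perturbation of the
#'   base composition.
#' @param rho genetic-chemical coupling in \[0, 1\]: 0 = chemistry ignores
#'   lineage, 1 = fully lineage-determined means.
#' @param colour_concordance probability that the colour label matches the
#'   individual's lineage.
#' @param ts_ratio transition:transversion ratio of the mutation model.
#' @return A list of class \code{sim_config}.
#' @export
simulation_config <- function(n_sites = 40, n_individuals = 250, K_lineages = 3,
                              loci = data.frame(
                                locus_id = c("mt1", "mt2", "nuc1", "nuc2"),
                                length = c(1056, 465, 791, 910),
                                mutation_scale = c(1.5, 1, 1, 1),
                                divergence = c(10, 6, 6, 8)),
                              bbox = c(-10, 30, 36, 60),
                              refugia = NULL, site_spread = 2.5,
                              contact_zone_width = 3,
                              n_compounds = 55, n_switch = 2,
                              chem_noise_sd = 0.35, lineage_effect = 0.8,
                              rho = 1, colour_concordance = 0.9,
                              ts_ratio = 2) {
  if (K_lineages < 1) stop("K_lineages must be >= 1", call. = FALSE)
  if (rho < 0 || rho > 1) stop("rho must be in [0, 1]", call. = FALSE)
  if (colour_concordance < 0 || colour_concordance > 1)
    stop("colour_concordance must be a probability", call. = FALSE)
  if (is.null(refugia)) {
    ang <- seq(0, 2 * pi, length.out = K_lineages + 1)[seq_len(K_lineages)]
    cx <- mean(bbox[1:2]); cy <- mean(bbox[3:4])
    refugia <- cbind(cx + 0.55 * (bbox[2] - cx) * cos(ang),
                     cy + 0.55 * (bbox[4] - cy) * sin(ang))
  }
  refugia <- matrix(refugia, ncol = 2)
  if (nrow(refugia) != K_lineages) stop("need one refugium per lineage", call. = FALSE)
  if (any(refugia[, 1] < bbox[1] | refugia[, 1] > bbox[2] |
            refugia[, 2] < bbox[3] | refugia[, 2] > bbox[4]))
    stop("refugium centroid outside bounding box", call. = FALSE)
  structure(as.list(environment()), class = "sim_config")
}

mutate_base <- function(base, ts_ratio = 2) {
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
  if (stats::runif(1) < ts_ratio / (ts_ratio + 1)) ts[[base]]
  else sample(tv[[base]], 1)
}

mutate_sites <- function(seqchars, sites, ts_ratio) {
  for (s in sites) seqchars[s] <- mutate_base(seqchars[s], ts_ratio)
  seqchars
}

#' Simulate a refugial phylogeography + chemotype dataset
#'
#' Sites are scattered around refugium centroids; each individual inherits
#' its site's home lineage, except near the equidistance line between two
#' refugia (the contact zone), where membership mixes with probability
#' rising to 1/2 at the line. Sequences follow a star phylogeny within
#' each lineage: lineage ancestors differ from a common root at disjoint
#' divergence sites, and each individual adds Poisson-many private
#' mutations (transition-biased). Chemical profiles are the convex
#' combination \code{(1 - rho) * base + rho * lineage mean} composition
#' with multiplicative lognormal noise, renormalised to 100%;
#' qualitative-switch compounds occur in exactly one lineage. Colour
#' labels match lineage with probability \code{colour_concordance}.
#'
#' @param cfg a [simulation_config].
#' @param seed integer RNG seed.
#' @return List of class \code{sim_dataset}: \code{alignments} (list of
#'   [seq_alignment]), \code{samples} (sample table), \code{chem}
#'   ([chem_profile]) and \code{truth} (latent assignments and the
#'   closed-form expectations used by validity checks).
#' @export
simulate_dataset <- function(cfg = simulation_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(seed)
  K <- cfg$K_lineages
  # --- sites around refugia ---------------------------------------------
  home <- rep_len(seq_len(K), cfg$n_sites)
  lon <- pmin(pmax(cfg$refugia[home, 1] + stats::rnorm(cfg$n_sites, 0, cfg$site_spread),
                   cfg$bbox[1]), cfg$bbox[2])
  lat <- pmin(pmax(cfg$refugia[home, 2] + stats::rnorm(cfg$n_sites, 0, cfg$site_spread),
                   cfg$bbox[3]), cfg$bbox[4])
  site_id <- sprintf("S%02d", seq_len(cfg$n_sites))
  dref <- sqrt(outer(lon, cfg$refugia[, 1], "-")^2 +
                 outer(lat, cfg$refugia[, 2], "-")^2)
  if (K == 1) {
    ord <- cbind(rep(1L, cfg$n_sites), rep(1L, cfg$n_sites))
    gap <- rep(Inf, cfg$n_sites)
  } else {
    ord <- t(apply(dref, 1, order))
    gap <- dref[cbind(seq_len(cfg$n_sites), ord[, 2])] -
      dref[cbind(seq_len(cfg$n_sites), ord[, 1])]
  }
  site_lineage <- ord[, 1]
  in_contact <- gap < cfg$contact_zone_width
  p_mix <- 0.5 * pmax(0, 1 - gap / cfg$contact_zone_width)
  # --- individuals -------------------------------------------------------
  n <- cfg$n_individuals
  ind_site <- rep_len(seq_len(cfg$n_sites), n)
  flip <- stats::runif(n) < p_mix[ind_site]
  ind_lineage <- ifelse(flip, ord[ind_site, 2], site_lineage[ind_site])
  ids <- sprintf("ind%03d", seq_len(n))
  # geo groups: split each lineage's sites into runs of ~3 by longitude
  geo_group_of_site <- character(cfg$n_sites)
  for (l in seq_len(K)) {
    ix <- which(site_lineage == l)
    sub <- ceiling(rank(lon[ix], ties.method = "first") / 3)
    geo_group_of_site[ix] <- sprintf("G%d_%d", l, sub)
  }
  colour_pool <- paste0("morph", seq_len(max(K, 2)))
  concord <- stats::runif(n) < cfg$colour_concordance
  colour <- ifelse(concord, colour_pool[ind_lineage],
                   colour_pool[1 + (ind_lineage %% max(K, 2))])
  samples <- validate_sample_table(data.frame(
    id = ids, site_id = site_id[ind_site],
    lat = lat[ind_site], lon = lon[ind_site],
    geo_group = geo_group_of_site[ind_site],
    colour_label = colour, lineage = ind_lineage,
    stringsAsFactors = FALSE))
  # --- sequences ---------------------------------------------------------
  alignments <- list()
  ancestors <- list()
  for (k in seq_len(nrow(cfg$loci))) {
    L <- cfg$loci$length[k]
    scale <- cfg$loci$mutation_scale[k]
    div <- cfg$loci$divergence[k]
    root <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    per_branch <- round(div / 2)
    div_sites <- sample.int(L, K * per_branch)
    anc <- lapply(seq_len(K), function(l)
      mutate_sites(root, div_sites[seq_len(per_branch) + (l - 1) * per_branch],
                   cfg$ts_ratio))
    seqs <- vapply(seq_len(n), function(i) {
      nmut <- stats::rpois(1, scale)
      s <- anc[[ind_lineage[i]]]
      if (nmut > 0)
        s <- mutate_sites(s, sample.int(L, min(nmut, L)), cfg$ts_ratio)
      paste(s, collapse = "")
    }, character(1))
    alignments[[cfg$loci$locus_id[k]]] <-
      seq_alignment(seqs, ids, cfg$loci$locus_id[k])
    ancestors[[cfg$loci$locus_id[k]]] <-
      vapply(anc, paste, character(1), collapse = "")
  }
  # --- chemistry ---------------------------------------------------------
  nc <- cfg$n_compounds
  base <- stats::rgamma(nc, shape = 0.5)
  base <- base / sum(base) * 100
  switch_ids <- matrix(sample.int(nc, K * cfg$n_switch), nrow = K)
  lin_mean <- matrix(0, K, nc)
  for (l in seq_len(K)) {
    m <- base * stats::rlnorm(nc, 0, cfg$lineage_effect)
    m[as.vector(switch_ids)] <- 0
    m[switch_ids[l, ]] <- 2                 # ~2% switch compounds, own lineage only
    lin_mean[l, ] <- m / sum(m) * 100
  }
  base_closed <- base
  base_closed[as.vector(switch_ids)] <- 0
  base_closed <- base_closed / sum(base_closed) * 100
  chem <- t(vapply(seq_len(n), function(i) {
    mu <- (1 - cfg$rho) * base_closed + cfg$rho * lin_mean[ind_lineage[i], ]
    x <- mu * stats::rlnorm(nc, 0, cfg$chem_noise_sd)
    x / sum(x) * 100
  }, numeric(nc)))
  dimnames(chem) <- list(ids, sprintf("cmp%02d", seq_len(nc)))
  truth <- list(
    site_lineage = stats::setNames(site_lineage, site_id),
    site_in_contact = stats::setNames(in_contact, site_id),
    ind_lineage = stats::setNames(ind_lineage, ids),
    refugia = cfg$refugia,
    switch_compounds = matrix(colnames(chem)[switch_ids], nrow = K),
    lineage_ancestors = ancestors,
    expected_between = stats::setNames(
      2 * round(cfg$loci$divergence / 2) + 2 * cfg$loci$mutation_scale,
      cfg$loci$locus_id),
    expected_within = stats::setNames(2 * cfg$loci$mutation_scale,
                                      cfg$loci$locus_id),
    seed = seed)
  structure(list(alignments = alignments, samples = samples,
                 chem = chem_profile(chem), truth = truth, config = cfg),
            class = "sim_dataset")
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' @param sim a \code{sim_dataset}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (aln in sim$alignments)
    write_fasta_alignment(aln, file.path(dir, paste0(aln$locus_id, ".fasta")))
  st <- sim$samples
  class(st) <- "data.frame"
  utils::write.csv(st, file.path(dir, "samples.csv"), row.names = FALSE)
  ch <- data.frame(id = rownames(sim$chem), unclass(sim$chem),
                   check.names = FALSE)
  utils::write.csv(ch, file.path(dir, "chem.csv"), row.names = FALSE)
  invisible(dir)
}

#' Independent null distance matrices
#'
#' Two Euclidean distance matrices from independent random point clouds —
#' the null case for Mantel / perMANOVA calibration.
#'
#' @param n number of labels (>= 4).
#' @param seed RNG seed.
#' @return list of two [dist_matrix] objects with common labels.
#' @export
simulate_null <- function(n, seed = 1) {
  if (n < 4) stop("n must be >= 4", call. = FALSE)
  set.seed(seed)
  lab <- paste0("s", seq_len(n))
  mk <- function() {
    p <- matrix(stats::runif(2 * n), n)
    d <- as.matrix(stats::dist(p))
    dimnames(d) <- list(lab, lab)
    dist_matrix(d)
  }
  list(a = mk(), b = mk())
}
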