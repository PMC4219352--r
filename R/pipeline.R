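#' Default pipeline configuration
#'
#' Returns the full parameter block of [run_pipeline] with defaults.
#' Either supply input paths (\code{fasta} named by locus, \code{samples},
#' \code{chem}) or set \code{simulate} to a [simulation_config] to run on
#' synthetic data.
#'
#' @param ... overrides of the default entries.
#' @return named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    fasta = NULL, samples = NULL, chem = NULL,   # input paths
    simulate = NULL,                             # or a simulation_config
    outdir = "phylochem-out",
    seed = 1,
    stages = c(popgen = TRUE, structure = TRUE, network = TRUE,
               landscape = TRUE, chemo = TRUE, compare = TRUE),
    gate_alpha = 0.05,        # global Phi_ST significance gate for SAMOVA
    gate_phi_floor = 0,       # optional Phi_ST magnitude floor (0 = off)
    gate_override = FALSE,    # TRUE: run SAMOVA on all loci regardless
    amova_n_perm = 10000,     # 1e5 as in large runs is available here
    samova_K = 3, samova_n_reps = 10, samova_n_steps = 10000,
    bootstrap_reps = 100,
    idw_a = 2, grid_cols = 150, margin = 0.05, use_residuals = TRUE,
    mask_hull = TRUE,
    chem_threshold = 0.1, nmds_k = 3, nmds_runs = 50,
    chem_n_perm = 10000, indval_n_perm = 999, indval_alpha = 0.05,
    bc_mode = "standardized",  # or "raw": Bray-Curtis on raw relative amounts
    mantel_n_perm = 10000)
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a YAML pipeline configuration
#' @param path YAML file whose keys mirror [pipeline_config].
#' @return a \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

chem_distance <- function(chem, threshold, bc_mode) {
  filt <- filter_compounds(chem, threshold)
  if (bc_mode == "raw") {
    list(filtered = filt, dm = bray_curtis(unclass(filt), shift = FALSE))
  } else {
    std <- transform_standardize(filt)
    list(filtered = filt, dm = bray_curtis(std, shift = TRUE))
  }
}

#' Run the full comparative phylogeography / chemometrics pipeline
#'
#' Stage order mirrors the analysis workflow: diversity statistics, then
#' population structure (loci whose global \eqn{\Phi_{ST}} fails the
#' significance gate are flagged and excluded from SAMOVA, overridable),
#' haplotype networks and the NJ tree, landscape surfaces (inter-individual
#' distance, residualized by default, and per-group diversity), the
#' chemometric battery (filter, transform, Bray-Curtis, nMDS, perMANOVA,
#' IndVal, dispersion, MMS surfaces), and the comparative Mantel layer
#' plus the diversity-variability regression. All tables are written as
#' TSV with embedded seed/parameters; surfaces as ESRI ASCII grids;
#' networks as GraphML; the tree as Newick. A YAML manifest records the
#' seed and full parameter set.
#'
#' @param cfg a [pipeline_config] (or YAML path).
#' @return A report list (per-stage results), invisibly; side effect: all
#'   outputs under \code{cfg$outdir}.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = cfg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
  }
  # ---- inputs -----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- simulate_dataset(cfg$simulate, seed = cfg$seed)
    alns <- sim$alignments; samples <- sim$samples; chem <- sim$chem
    report$truth <- sim$truth
  } else {
    if (is.null(cfg$samples)) stop("no samples table and no simulation", call. = FALSE)
    samples <- read_sample_table(cfg$samples)
    alns <- NULL
    if (!is.null(cfg$fasta)) {
      alns <- lapply(seq_along(cfg$fasta), function(k)
        read_fasta_alignment(cfg$fasta[[k]], names(cfg$fasta)[k]))
      names(alns) <- names(cfg$fasta)
    }
    chem <- if (!is.null(cfg$chem)) read_chem_matrix(cfg$chem) else NULL
  }
  if (!is.null(alns) && !is.null(chem)) {
    ov <- sample_overlap(genetic = Reduce(union, lapply(alns, `[[`, "sample_ids")),
                         chemical = rownames(chem), table = samples$id)
    report$overlap <- ov
    n_miss <- vapply(ov$missing, length, integer(1))
    if (any(n_miss > 0))
      message("partial sample overlap: ",
              paste(sprintf("%s lacks %d", names(n_miss), n_miss), collapse = "; "))
  }
  site_map <- stats::setNames(samples$site_id, samples$id)
  group_map <- stats::setNames(samples$geo_group, samples$id)
  site_coords <- unique(samples[, c("site_id", "lon", "lat")])
  # ---- popgen -----------------------------------------------------------
  if (cfg$stages[["popgen"]] && !is.null(alns)) {
    report$diversity <- stage("popgen", diversity_by_group(alns, samples))
    write_stats_tsv(report$diversity, file.path(cfg$outdir, "diversity.tsv"),
                    seed = cfg$seed)
    report$gen_dist <- stage("popgen", pairwise_p_distance(alns))
  }
  # ---- structure --------------------------------------------------------
  if (cfg$stages[["structure"]] && !is.null(alns)) {
    report$global_phi <- lapply(alns, function(aln) stage("structure", {
      mm <- pairwise_mismatch_matrix(aln)
      global_phi_st(mm, site_map[aln$sample_ids],
                    n_perm = cfg$amova_n_perm, seed = cfg$seed)
    }))
    gate <- vapply(report$global_phi, function(g)
      !is.na(g$p_value) && g$p_value < cfg$gate_alpha &&
        abs(g$phi_st) >= cfg$gate_phi_floor, logical(1))
    report$samova_gate <- gate
    if (any(!gate))
      message("loci failing the structure gate (flagged, excluded from SAMOVA): ",
              paste(names(alns)[!gate], collapse = ", "))
    run_these <- if (cfg$gate_override) names(alns) else names(alns)[gate]
    report$samova <- lapply(alns[run_these], function(aln) stage("structure", {
      mm <- pairwise_mismatch_matrix(aln)
      samova(mm, site_coords, site_map, K = cfg$samova_K,
             n_reps = cfg$samova_n_reps, n_steps = cfg$samova_n_steps,
             seed = cfg$seed)
    }))
    phi_tab <- data.frame(
      locus = names(alns),
      phi_st = vapply(report$global_phi, `[[`, numeric(1), "phi_st"),
      p = vapply(report$global_phi, `[[`, numeric(1), "p_value"),
      gate_passed = gate)
    write_stats_tsv(phi_tab, file.path(cfg$outdir, "global_phi_st.tsv"),
                    seed = cfg$seed, params = cfg[c("amova_n_perm", "gate_alpha")])
    sam_tab <- do.call(rbind, lapply(names(report$samova), function(nm) {
      p <- report$samova[[nm]]
      data.frame(locus = nm, K = p$K, site = names(p$assignment),
                 group = unname(p$assignment), phi_ct = p$phi[["phi_ct"]])
    }))
    if (!is.null(sam_tab))
      write_stats_tsv(sam_tab, file.path(cfg$outdir, "samova.tsv"),
                      seed = cfg$seed,
                      params = cfg[c("samova_K", "samova_n_reps", "samova_n_steps")])
  }
  # ---- haplotype networks and tree -------------------------------------
  if (cfg$stages[["network"]] && !is.null(alns)) {
    report$networks <- lapply(alns, function(aln) stage("network", {
      hs <- collapse_haplotypes(aln, groups = group_map)
      if (length(hs$haplotypes) >= 2) median_joining_network(hs) else NULL
    }))
    for (nm in names(report$networks))
      if (!is.null(report$networks[[nm]]))
        write_haplonet_graphml(report$networks[[nm]],
                               file.path(cfg$outdir, paste0("network_", nm, ".graphml")))
    report$tree <- stage("network",
      bootstrap_support(alns, n_reps = cfg$bootstrap_reps, seed = cfg$seed))
    write_newick(report$tree, file.path(cfg$outdir, "nj_tree.nwk"))
  }
  # ---- landscape surfaces ----------------------------------------------
  if (cfg$stages[["landscape"]] && !is.null(alns)) {
    report$surfaces <- stage("landscape", {
      net <- build_connectivity(site_coords)
      mids <- edge_midpoint_values(net, report$gen_dist, site_map)
      if (cfg$use_residuals) mids <- residualize(mids, site_coords)
      gd_surf <- idw_surface(mids, a = cfg$idw_a, grid_cols = cfg$grid_cols,
                             margin = cfg$margin, mask_hull = cfg$mask_hull)
      write_ascii_grid(gd_surf, file.path(cfg$outdir, "genetic_distance.asc"))
      div <- report$diversity
      mean_pi <- tapply(div$pi, div$geo_group, mean, na.rm = TRUE)
      bary <- group_barycenters(samples)
      dv_surf <- diversity_surface(mean_pi, bary, a = cfg$idw_a,
                                   grid_cols = cfg$grid_cols, margin = cfg$margin,
                                   mask_hull = cfg$mask_hull)
      write_ascii_grid(dv_surf, file.path(cfg$outdir, "genetic_diversity.asc"))
      list(distance = gd_surf, diversity = dv_surf, network = net, midpoints = mids)
    })
  }
  # ---- chemometrics -----------------------------------------------------
  if (cfg$stages[["chemo"]] && !is.null(chem)) {
    report$chem <- stage("chemo", {
      cd <- chem_distance(chem, cfg$chem_threshold, cfg$bc_mode)
      nm <- chem_nmds(cd$dm, k = cfg$nmds_k, n_runs = cfg$nmds_runs,
                      seed = cfg$seed)
      grp <- group_map[rownames(cd$dm)]
      keep <- names(grp)[grp %in% names(which(table(grp) >= 2))]
      pm <- permanova(cd$dm[keep, keep], group_map[keep],
                      n_perm = cfg$chem_n_perm, seed = cfg$seed)
      iv <- indval(unclass(cd$filtered)[keep, , drop = FALSE], group_map[keep],
                   n_perm = cfg$indval_n_perm, alpha = cfg$indval_alpha,
                   seed = cfg$seed)
      dt <- dispersion_test(cd$dm[keep, keep], group_map[keep],
                            n_perm = cfg$indval_n_perm, seed = cfg$seed)
      list(dm = cd$dm, filtered = cd$filtered, nmds = nm, permanova = pm,
           indval = iv, dispersion = dt)
    })
    write_stats_tsv(data.frame(id = rownames(report$chem$nmds$points),
                               report$chem$nmds$points),
                    file.path(cfg$outdir, "nmds_coordinates.tsv"),
                    seed = cfg$seed,
                    params = list(k = cfg$nmds_k, runs = cfg$nmds_runs,
                                  stress = report$chem$nmds$stress))
    ivt <- data.frame(compound = names(report$chem$indval$p),
                      group = report$chem$indval$max_group,
                      indval = apply(report$chem$indval$indval, 2, max),
                      p = report$chem$indval$p,
                      significant = report$chem$indval$significant)
    write_stats_tsv(ivt, file.path(cfg$outdir, "indval.tsv"), seed = cfg$seed,
                    params = cfg[c("indval_n_perm", "indval_alpha")])
    write_stats_tsv(data.frame(group = names(report$chem$dispersion$variability),
                               variability = as.numeric(report$chem$dispersion$variability)),
                    file.path(cfg$outdir, "mms_variability.tsv"), seed = cfg$seed)
    # MMS surfaces (distance + variability)
    report$chem_surfaces <- stage("chemo", {
      net <- build_connectivity(site_coords)
      ids <- intersect(rownames(report$chem$dm), names(site_map))
      mids <- edge_midpoint_values(net, report$chem$dm[ids, ids], site_map)
      if (cfg$use_residuals) mids <- residualize(mids, site_coords)
      ds <- idw_surface(mids, a = cfg$idw_a, grid_cols = cfg$grid_cols,
                        margin = cfg$margin, mask_hull = cfg$mask_hull)
      write_ascii_grid(ds, file.path(cfg$outdir, "mms_distance.asc"))
      vr <- report$chem$dispersion$variability
      bary <- group_barycenters(samples)
      vs <- diversity_surface(vr, bary, a = cfg$idw_a,
                              grid_cols = cfg$grid_cols, margin = cfg$margin,
                              mask_hull = cfg$mask_hull)
      write_ascii_grid(vs, file.path(cfg$outdir, "mms_variability.asc"))
      list(distance = ds, variability = vs)
    })
  }
  # ---- comparative layer ------------------------------------------------
  if (cfg$stages[["compare"]] && !is.null(alns) && !is.null(chem)) {
    report$comparative <- stage("compare", {
      geo <- geographic_distance_matrix(samples)
      col <- colour_distance_matrix(samples)
      bat <- mantel_battery(report$gen_dist, report$chem$dm, col, geo,
                            n_perm = cfg$mantel_n_perm, seed = cfg$seed)
      write_stats_tsv(bat, file.path(cfg$outdir, "mantel_tests.tsv"),
                      seed = cfg$seed, params = list(n_perm = cfg$mantel_n_perm))
      div <- report$diversity
      mean_pi <- tapply(div$pi, div$geo_group, mean, na.rm = TRUE)
      reg <- tryCatch(
        diversity_variability_regression(mean_pi,
                                         report$chem$dispersion$variability),
        error = function(e) NULL)
      list(mantel = bat, regression = reg)
    })
  }
  # ---- manifest ---------------------------------------------------------
  manifest <- list(package_version = as.character(utils::packageVersion("phylochem")),
                   seed = cfg$seed,
                   parameters = cfg[setdiff(names(cfg), c("stages", "simulate"))],
                   stages = as.list(cfg$stages))
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))
  invisible(report)
}
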