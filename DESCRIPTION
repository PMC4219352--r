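Package: phylochem
Title: Comparative Phylogeography and Chemical-Signal Divergence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end toolkit for comparative phylogeography of
    European bumblebee populations and the divergence of their male
    marking secretions (MMS). Implements per-locus haplotype collapsing
    and diversity statistics (haplotype and nucleotide diversity,
    parsimony-informative sites), AMOVA Phi-statistics with permutation
    tests, spatial AMOVA (SAMOVA) by simulated annealing over
    geographically contiguous site partitions, median-joining haplotype
    networks with transversion weighting, neighbour-joining trees with
    bootstrap support, landscape interpolation surfaces of genetic and
    chemical distance and diversity (Delaunay connectivity, edge-midpoint
    assignment, inverse-distance weighting), a compositional chemometric
    battery on relative-amount profiles (filtering, transformation,
    Bray-Curtis ordination, perMANOVA, multivariate dispersion, indicator
    compounds), Mantel and partial Mantel comparative tests, and a
    synthetic-data generator emulating refugial lineages, contact zones
    and chemotype switches for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    grDevices,
    igraph,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
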