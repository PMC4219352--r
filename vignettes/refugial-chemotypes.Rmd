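---
title: "Comparative phylogeography and chemical-signal divergence: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative phylogeography and chemical-signal divergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylochem)
```

## The scientific problem

Widespread European temperate species typically survived Pleistocene
glaciations in southern refugia (Iberia, Italy, the Balkans) or in cryptic
central/eastern refugia, diverging in allopatry and meeting again along
postglacial recolonization routes. For bumblebees, this history can leave a
double signature: neutral genetic structure (mitochondrial and nuclear
haplogroups tied to refugia, endemic island haplotypes, contact zones), and
divergence in a sexually selected trait — the male marking secretion (MMS),
the compositional blend of cephalic labial gland compounds that males
deposit to attract conspecific females. `phylochem` implements the full
comparative pipeline for such a study: per-locus population-genetic
statistics, AMOVA/SAMOVA spatial structure, haplotype networks and trees,
landscape interpolation surfaces, a compositional chemometric battery, and
the Mantel-based layer that ties geography, genes, colour patterns and
chemistry together. A synthetic-data generator with known truth makes every
stage testable end to end.

## Genetic statistics

**Haplotypes and diversity.** Haplotype identity is exact string match
after uppercasing; the intended alignments carry no indels, so no
indel-aware collapsing is attempted. Haplotype diversity uses Nei's
unbiased estimator $\hat h = \frac{n}{n-1}(1 - \sum_i p_i^2)$; nucleotide
diversity is the mean per-site pairwise difference
$\pi = \frac{2}{n(n-1)} \sum_{i<j} d_{ij}/L_{ij}$ with *pairwise* deletion:
each pair is compared only at sites where both members carry an unambiguous
base ($L_{ij}$), matching the default behaviour of the standard desktop
tools for these statistics. A site is parsimony-informative when at least
two states each occur in at least two sequences, gaps and `N` excluded.

**Distances.** Two inter-individual distances are used downstream, and
they differ on purpose. The AMOVA/SAMOVA layer uses the *number of
mismatches* unscaled — the convention in which squared molecular distance
equals mismatch count. The cartography and Mantel layers use *p-distances*
(mismatches over comparable sites), averaged unweighted across the loci a
pair shares; a pair covered by no locus is an error, never a silent NA.

**Molecular clock.** `clock_divergence_time()` is exact division of a
percentage divergence by a rate (default 2% per Myr, the insect
mitochondrial convention). One published conversion in this literature
(9.68% at 2%/Myr reported as "~4.9 Mya") is inconsistent with exact
division (4.84); the function does not reproduce the discrepancy.
`round_half_up()` provides the half-away-from-zero decimal convention used
for reported summaries (0.505 → 0.51), which base `round()` does not.

## AMOVA, and SAMOVA's annealing search

The hierarchical decomposition follows the standard sums-of-squared-
deviations route: for any set $S$,
$SSD(S) = \frac{1}{2|S|}\sum_{i,j \in S} d^2_{ij}$, decomposed into
among-group, among-population-within-group and within-population
components via the usual unbalanced-design coefficients, yielding
$\Phi_{CT} = \sigma^2_a/\sigma^2_T$,
$\Phi_{SC} = \sigma^2_b/(\sigma^2_b + \sigma^2_c)$ and
$\Phi_{ST} = (\sigma^2_a+\sigma^2_b)/\sigma^2_T$. Components can be
negative in finite samples and are deliberately not clamped. Significance
uses three permutation schemes — individuals within groups
($\Phi_{SC}$), whole populations among groups ($\Phi_{CT}$), individuals
among populations among groups ($\Phi_{ST}$) — each with the
$(\mathrm{hits}+1)/(N+1)$ correction. When every population is its own
group the two-level design collapses analytically to the one-level
$\Phi_{ST}$, which the tests assert.

SAMOVA treats each sampling site as a population and searches for the
$K$-group partition of sites maximizing $\Phi_{CT}$, constrained to be
geographically contiguous under the Delaunay triangulation of the site
coordinates (the published description of the method uses Voronoi
adjacency, its dual; Delaunay keeps the module consistent with the
cartography layer). The search is simulated annealing over single-site
reassignments to adjacent groups that keep the donor group connected.
Because the paper states only the step and repetition counts, the schedule
itself is this package's choice: the initial temperature is set from ~30
pilot moves so that a move of typical magnitude is accepted with
probability ~0.8, cooling geometrically to $10^{-3}$ of that over the run;
the best state ever visited across repetitions is returned. With sites as
populations the $\Phi_{CT}$ of a candidate partition reduces to block sums
of the squared-distance matrix, so a move is scored in $O(S^2)$
independent of sample size. For $\le 8$ sites the tests compare the
attained optimum against exhaustive enumeration of contiguous partitions;
a scan over $K$ flags (never auto-drops) partitions containing single-site
groups.

## Haplotype networks and trees

The median-joining construction operates under a weighted Hamming
distance: transitions cost 1, transversions 2 by default (configurable),
indels default to the transversion cost. Each round builds the minimum
spanning network (every edge of every minimum spanning tree; `epsilon`
relaxes the threshold and is 0 by default, as in the reference desktop
implementation), proposes the per-site consensus of every node triplet,
and adds the median that most shortens the total spanning length; when no
median improves the length, medians whose removal leaves it unchanged are
pruned. Three-way ties at a site resolve toward the state minimizing the
summed weighted cost to the triplet, then lexicographically. Median
vectors carry zero observed frequency — they stand for unsampled or
extinct intermediates. Networks are built per locus; a combined-locus
network is intentionally not offered.

Neighbour-joining delegates the Saitou–Nei agglomeration to `ape::nj`,
then clamps any negative branch to zero, moving the deficit onto the
sister branch so leaf-to-leaf path lengths are preserved. Bootstrap
support resamples sites with replacement within each locus, rebuilds the
averaged p-distance matrix and tree per replicate, and reports the
percentage of replicates containing each internal bipartition.

## Landscape surfaces

The cartography follows the connectivity-network interpolation idea:
inter-individual distances are assigned to the midpoints of Delaunay
edges (the mean over all sample pairs spanning the edge's two sites),
optionally residualized against great-circle inter-site distance by OLS
to remove the isolation-by-distance trend, then interpolated by inverse
distance weighting, $\hat v = \sum w_i v_i / \sum w_i$ with
$w_i = d_i^{-a}$ and $a = 2$. Per-group diversity (mean $\pi$ across
loci) or MMS variability is interpolated the same way from values placed
at group barycenters (plain means of the distinct site coordinates in the
group).

Numerical choices: all planar geometry (triangulation, IDW distances)
runs on an equirectangular projection about the mean latitude — adequate
at a European extent; only the regression predictor uses great-circle
kilometres (haversine, 6371-km sphere). Longitude translations leave
surfaces unchanged exactly; latitude translations change the projection
scale slightly, which is accepted. The grid defaults to 150 columns with
a 5% margin; cells outside the convex hull of the input points (expanded
by the margin) are masked so the surface never extrapolates, and a grid
node within $10^{-9}$ degrees of a data point takes that point's value
exactly. IDW values are convex combinations, so every surface is bounded
by the input extrema — asserted as a property test, along with agreement
with direct summation at probe nodes and near-nearest-neighbour behaviour
at $a = 50$. The Delaunay triangulation itself is a Bowyer–Watson
implementation validated against an $O(n^4)$ empty-circumcircle oracle;
duplicate site coordinates are jittered by $10^{-6}$ degrees with a
warning. Exactly cocircular quadruples make the triangulation (and its
edge count) non-unique; sampling coordinates in practice are never
cocircular and test fixtures avoid them.

## The chemometric battery

Compounds whose relative amount never reaches 0.1% in any sample are
discarded (boundary inclusive); remaining rows are deliberately *not*
renormalized, since the removed mass is trace. The published description
of the transformation ("log (x−1)") is arithmetically impossible for
relative amounts ≤ 1%; it is implemented as the standard compositional
damping $y = \log_{10}(x+1)$, followed by per-compound standardization to
mean 0, sd 1 (zero-variance compounds become all-zeros with a warning).

Bray–Curtis requires non-negative input, but the standardized matrix has
negatives. The package's primary mode shifts the standardized matrix by
its global minimum before computing Bray–Curtis; a second mode computes
Bray–Curtis on the untransformed relative amounts. Both are exposed
(`bc_mode`) because the source analysis does not pin the choice; this is
the largest genuinely open decision in the pipeline and both modes are
exercised wherever published statistics are checked.

Ordination is Kruskal stress-1 nMDS (`vegan::monoMDS`), three dimensions,
50 starts by default: the first from the metric (PCoA) configuration, the
rest random, keeping the lowest stress. perMANOVA delegates to
`vegan::adonis2` (free label permutation, no strata) and its pseudo-F is
asserted to equal the classical one-way ANOVA F on univariate Euclidean
fixtures to $10^{-10}$; pairwise tests are Bonferroni-corrected, as
stated. IndVal is specificity × fidelity × 100 with significance by label
randomization of each compound's maximum group value, presence meaning
strictly positive relative amount in the filtered (untransformed) matrix.

The dispersion (variability) statistic embeds the distance matrix by
principal coordinates, keeps negative-eigenvalue axes with negative sign
(so squared distances are reproduced exactly), and measures each sample's
distance to its group centroid; the per-group mean is the "MMS
variability" used in maps and the regression. The observed distances and
F match `vegan::betadisper(type = "centroid")` exactly (asserted in a
test). The permutation p-value, however, permutes *group labels and
re-estimates centroids and distances under each permutation* rather than
permuting the fixed observed distances: the fixed-distance scheme is
measurably anticonservative for small groups (distances encode the
original grouping through centroid estimation), while the re-estimating
scheme is exact under an exchangeable null. Its calibration is asserted
at nominal 5% over null replicates. A Pearson-correlation distance mode
exists for completeness but the Bray–Curtis/PCoA route is primary.

## The comparative layer

Geographic distance is haversine km between individuals; colour distance
is binary (0 same colour pattern, 1 different). Mantel tests correlate
off-diagonal entries (Pearson) with one-tailed upper p-values by
simultaneous row/column permutation of the second matrix — one-tailed
because the tested hypotheses are positive associations; a two-tailed
variant is a flag away. The partial Mantel statistic is the closed-form
first-order partial correlation, equal to the residual-regression route
(asserted to $10^{-10}$); by convention the second matrix is the one
permuted. `mantel_battery()` runs the six plain and three partial tests
in a fixed order. The diversity–variability relation is a Gaussian
identity-link linear model of per-group MMS variability on per-group mean
$\pi$ — the cited analysis is a GLM with nothing suggesting a
non-Gaussian family — with single-sample groups excluded upstream because
their diversity is undefined.

## The synthetic generator

`simulate_dataset()` emulates the statistical structure the analysis
assumes, not demographic realism. Sites scatter (Gaussian, sd 2.5°)
around K refugium centroids inside a European-scale box; each site's home
lineage is its nearest refugium, and individuals near the equidistance
line between two refugia switch lineage with probability rising to 1/2 at
the line (the contact zone, width 3° by default). Sequences follow a
star phylogeny within lineages: lineage ancestors differ from a common
root at disjoint divergence sites (so the expected between-lineage
mismatch count is the configured divergence plus twice the within-lineage
scale, a closed form the tests check to 10% over 50 replicates), and each
individual adds Poisson-many private mutations with a 2:1
transition:transversion bias so the network weighting is exercised.
Chemical profiles are the convex combination
$(1-\rho)\,\mathrm{base} + \rho\,\mathrm{lineage\ mean}$ with
multiplicative lognormal noise, renormalized to 100%; a few
qualitative-switch compounds occur in exactly one lineage, mirroring the
diagnostic-compound pattern seen in real chemotypes; colour labels match
lineage with probability 0.9. Defaults (40 sites, 250 individuals, four
loci of 1056/465/791/910 bp, 55 compounds) mirror the scale of the
motivating study.

What the generator does *not* emulate — coalescent genealogies,
recombination, migration beyond contact-zone mixing, compound families
with correlated abundances, instrument noise — bounds what green tests
mean: they validate the estimators and the pipeline plumbing under the
assumed structure, not robustness to every feature of real data.

`simulate_null()` provides independent random distance matrices as the
calibration null for the permutation tests; Mantel, perMANOVA, dispersion
and AMOVA are each required to hold empirical type-I error within
[0.03, 0.07] at nominal 5%. The calibration uses 500 replicates of
16-sample fixtures with 99 permutations — sizes chosen for power against
the band width at an affordable runtime.

## Problem sizes and determinism

The test suite runs scaled-down instances (alignments of tens of samples
and a few hundred bp, 8–14 sites, annealing runs of a few hundred steps,
20-seed replicate loops); the acceptance script runs a 100-individual,
20-site, two-locus study with 999-permutation tests. Large published-scale
settings (10 000 annealing steps × 10 repetitions, 10 000–100 000
permutations) remain the function defaults or config options. Every
stochastic routine takes an explicit seed; a pipeline rerun under the same
seed is byte-identical, and every TSV embeds its seed and parameters.

## Known limitations

* Exact reproduction of the published MMS statistics requires the study's
  supplementary relative-amount matrix and sampling table, and the genetic
  counterparts require the archived sequence accessions; neither ships
  with the package. The acceptance tests state precisely where to place
  these files to activate those checks.
* The equirectangular planar approximation degrades toward the poles and
  for continental-scale longitude spans.
* Median-joining is greedy (one best median per round); for tie-rich data
  the published closed-source tool may return a different, equally short
  network.
* The dispersion test assumes exchangeable samples under the null; with
  strong location differences between groups its permutation null mixes
  location and dispersion, a caveat shared with the method it implements.
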