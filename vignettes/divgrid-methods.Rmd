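---
title: "Grid-based mapping of SSR diversity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grid-based mapping of SSR diversity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divgrid)
```

divgrid maps the genetic diversity of georeferenced, diploid SSR
(microsatellite) collections onto a regular grid, corrects the strong and
uneven sampling bias typical of germplasm collections, and characterizes
population structure (clusters, their memberships and distances, spatial
PCA, isolation by distance). This vignette is the package's own account of
the statistical machinery, the tunable parameters, and the design decisions
taken where more than one defensible choice existed.

## The mapping model: circular neighborhoods on a 10-arcminute grid

The unit of analysis is a 10-arcminute grid cell (~18 km at the equator),
aligned to the global origin (-180, -90) so cell indices are reproducible
across datasets. Collections are sparse points, so each sampled tree is
taken as representative of the circular area of one decimal degree diameter
(~111 km at the equator) around it: `replicate_samples()` places every
individual into each cell whose *center* lies within 0.5 degrees (planar
Euclidean distance in degrees, inclusive) of the individual's location. On a
10-arcminute lattice a disc of radius 0.5 degrees contains at most 29 cell
centers, so each tree is replicated into up to 29 cells; the replication
factor shrinks at the grid-extent margin.

Two geometric conventions matter and are fixed throughout:

* cells are half-open intervals `[west, east) x [south, north)`, so a point
  on a boundary belongs to exactly one cell;
* distances are planar in decimal degrees, appropriate for the equatorial
  study regions this design targets; a great-circle option exists only for
  the Mantel geographic distance, where the choice is isolated.

The cell-intersects-disc alternative ("any part of the cell inside the
neighborhood") would add a ragged one-cell fringe; cell-center inclusion
reproduces the point-symmetric disc and keeps the replicate count bounded
and interpretable.

## Sample-bias correction by repeated subsampling

After replication, per-cell sample sizes still vary over orders of
magnitude. All per-cell statistics are therefore computed as the mean over
`B = 1000` subsamples of `n_trees = 8` individuals (16 gene copies) drawn
*without replacement*, and cells with fewer than 8 trees are discarded. The
8-tree threshold follows the rule of setting the common sample size to the
median of the per-cell counts (`filter_cells(min_trees = "auto")`); the
explicit value 8 reproduces the published analysis this pipeline
re-implements.

Subsampling operates on whole trees rather than on gene copies so that
observed heterozygosity — a property of the diploid genotype — survives the
correction. For allelic richness the procedure has an analytic counterpart,
the hypergeometric rarefaction expectation at `g` copies,

$$E[\text{alleles}] = \sum_i \left[ 1 - \binom{N - N_i}{g} \Big/
\binom{N}{g} \right],$$

implemented in `rarefaction_expected_alleles()` and used as the package's
built-in oracle: `validate_against_rarefaction()` regresses bootstrap means
on the closed form across cells. Subsampling trees and subsampling copies
differ only through within-individual allele pairing; on single-gene-pool
(HWE) cells the regression attains slope and correlation above 0.99, which
`scripts/acceptance.R` recomputes end to end, and the test suite asserts
exact (3 Monte-Carlo-SE) unbiasedness for the copy-level draw plus a small
pairing allowance (0.05 alleles/locus) for the tree-level draw. On cells
mixing several gene pools the pairing effect grows (a Wahlund-type excess of
homozygosity), which is a property of the data, not an estimator defect.

Determinism: every unit draws its subsamples from an RNG stream seeded by a
hash of (master seed, unit key), so results are independent of cell
iteration order and of row order within cells; the hot loop runs in
compiled code and is cross-checked in the tests against a plain-R
re-evaluation on identical subsample indices.

## The statistic set

Per sample (cell or cluster), means over non-empty loci of: allelic
richness; Shannon information index ($-\sum p \ln p$); Nei gene diversity
($1 - \sum p^2$, plug-in form — no $2n/(2n-1)$ correction, because size
correction is done by the subsampling itself); observed heterozygosity;
locally common alleles; private alleles. Loci with no data in a sample are
skipped rather than imputed as zero, so missing data never deflate
diversity.

Locally common alleles follow Frankel's idea of alleles that are
geographically restricted yet frequent where they occur. Two conventions are
implemented exactly as they differ between the grid and cluster analyses:

* grid mode: allele present in at most 25% of retained cells, with
  within-cell frequency `>= 5%` (inclusive);
* cluster mode: allele present in one or two clusters, with within-cluster
  frequency strictly `> 5%`.

The occupancy criterion is evaluated once on the full (non-subsampled) unit
spectra — occupancy is a global property of the map — while the frequency
criterion is re-evaluated inside every subsample and averaged. Private
alleles (single-unit alleles) use the same global-occupancy logic with
threshold one.

## Cluster analysis

`build_allele_matrix()` encodes genotypes as allele dosages (homozygote 1,
heterozygote 0.5/0.5; missing loci mean-imputed), the standard PCA-ready
representation. Cluster discovery runs k-means (best of 30 starts) on
retained PCA scores for each k and scores solutions with
$BIC(k) = n \ln(WSS_k/n) + k \ln n$.

Two retention/selection choices were genuinely open:

* *How many PCs to feed k-means.* Retaining PCs up to 95% variance keeps
  hundreds of near-noise axes whose summed within-cluster variance swamps
  the between-cluster signal and flattens the BIC curve. The default is the
  Kaiser rule (axes with above-average eigenvalue); the 95% rule remains
  available (`n_pcs = "auto"`) and is the default where it is harmless and
  conventional (DAPC).
* *Reading the elbow.* The suggestion is the first flattening: the smallest
  k whose next BIC improvement falls below 5% of the curve's range. A raw
  max-second-difference rule misfires while the curve is still descending
  steeply, and an interior-minimum rule chases negligible dips in noisy
  plateaus. Whatever the suggestion, the full curve is returned and k is
  user-confirmable, which mirrors how these scans are used in practice.

Membership probabilities come from DAPC: linear discriminant analysis on the
retained PC scores with uniform priors, so memberships are Gaussian
posteriors under a shared within-group covariance. They are proximities to
clusters, not admixture coefficients. Cluster-level statistics use only
individuals with membership `>= 0.7` (inclusive) and are bootstrap-corrected
with `n_trees` equal to the smallest retained cluster.

Between-cluster divergence is Nei's (1972) standard distance with J
statistics pooled over loci, $D = -\ln(J_{xy}/\sqrt{J_x J_y})$, summarized
by a complete-linkage dendrogram whose fidelity is reported as the
cophenetic correlation. D is not guaranteed metric (the triangle inequality
can fail), which is documented rather than "fixed". Disjoint allele sets
give an infinite distance with a warning. For individual-level
isolation-by-distance tests each individual is treated as a two-copy
population under the same formula (mean-imputed dosages), and the Mantel
test compares genetic with geographic distance using one-sided permutation
p-values $p = (1 + \#\{r_\pi \ge r\})/(1 + B)$.

## Spatial PCA

The sPCA eigen-decomposes $C = X^\top \tilde W X / n$, where $X$ is the
column-centered allele matrix and $\tilde W$ the symmetrized, row-normalized
Delaunay adjacency of the sampling locations (duplicate coordinates are
jittered by at most 1e-6 degrees under a fixed seed). Each axis score
$s = Xv$ satisfies $\lambda = \mathrm{var}(s) \cdot I(s)$ with $I$ Moran's
coefficient — positive eigenvalues are global (cline/patch) structures,
negative ones local (neighbor-dissimilarity) structures — and the
eigenvalues sum to $\mathrm{tr}(C)$. Both identities are asserted to 1e-8
in the tests. The significance of global/local structure is assessed by
permuting individuals' locations, with the positive (resp. absolute
negative) eigenvalue mass as the test statistic; the cited methodology does
not name its exact statistic, and eigenvalue mass is the natural choice
given the decomposition. Scores are mapped by assigning each cell the mean
score of individuals within the 1-degree circular neighborhood of its
*center* — note the direction: diversity surfaces replicate trees into
cells, score and membership surfaces gather individuals around cell
centers; the two constructions coincide on symmetric configurations and are
tested against brute-force enumeration separately.

## Raster products

All map products are deterministic functions of their inputs on the shared
cell lattice: diversity surfaces (one value per retained cell), per-cluster
membership surfaces (per cell, the *maximum* membership among in-range
individuals with membership `>= 0.7`, so values are in [0.7, 1]), and the
cluster-richness surface (count of clusters with data per cell). Interchange
is the ESRI ASCII grid: plain text, north-to-south rows, nodata -9999, six
significant digits.

## The synthetic-data generator

The generator is the package's study system: it emulates the statistical
structure the analysis assumes, with known truth for recovery tests.

* *Drift.* Ancestral allele frequencies per locus are symmetric Dirichlet(1)
  draws over 8-16 alleles; population frequencies follow a Balding-Nichols
  Dirichlet, `Dirichlet(p_anc (1-F)/F)`. `F = 0.2` gives differentiated but
  internally diverse populations; `F = 0.8` produces the near-fixation
  signature of bottlenecked cultivated lineages.
* *Space.* Individuals are bivariate-normal around refugium centers
  (`spatial_sd` 0.8 degrees by default) in an equatorial box
  (-80..-45 lon, -20..10 lat), so the planar-degree distance convention
  holds as in the target study region.
* *Isolation by distance.* A fraction `admix_frac = 0.3` of each
  individual's gene pool is a mixture of all population pools with weights
  decaying as `exp(-d / ibd_mixing)` in the distance to each center; the
  remaining 70% always comes from the individual's own population. Geography
  thus decides *which* foreign pools leak in while the admixture fraction
  stays bounded — producing a clear Mantel signal without dissolving the
  cluster structure. A pure distance-softmax made individuals between
  co-located centers majority-foreign, which is not the
  differentiated-clusters regime being emulated.
* *Sampling bias.* The benchmark scenario (`cacao_like_scenario()`: 939
  individuals, 96 loci, 10 populations) samples the four populations
  overlapping a north-west hotspot region 2.5x as densely each, making the
  region's collecting density an order of magnitude above the rest of the
  range while keeping any single cluster below ~16% of the dataset. Two
  margin populations are bottlenecked (`F = 0.8`). Missing genotype pairs
  are masked at 2%.

What the generator does *not* emulate: mutation models (stepwise or
otherwise), coalescent genealogy, linkage, null alleles and genotyping
error, temporal dynamics, and real landscape barriers. Passing recovery
tests on this generator therefore shows the pipeline recovers the structure
it models — drifted HWE clusters with distance-decaying admixture — not that
it is robust to every artifact of real SSR panels.

## Problem sizes and numerical choices

The validation study behind the reported slope/correlation uses ten
`F = 0.2` populations of 50 individuals each on non-overlapping ranges
(so each retained cell samples one HWE gene pool), 96 loci, no missing
data, cells retained at 8 trees, `B = 1000`, and the regression taken over
300 cells drawn deterministically from the ~700 retained — comfortably
above the 100-cell floor the validation design calls for. Type-I error of
the Mantel and sPCA permutation tests is checked at 800 null simulations
with 99 permutations each; the Monte-Carlo Mantel p-value is compared with
the exhaustive 5!-permutation null at n = 5.

Remaining numerics: `0 ln 0 = 0` in the Shannon index; `lchoose` for the
rarefaction binomials; eigen-decompositions on the symmetrized matrix with
a dual n-by-n route when columns outnumber rows; hclust's standard
lowest-index tie-break; an LDA ridge only if the within-group covariance is
singular (collinear score columns are dropped first); reverse-jackknife
outlier flagging on sorted unique values with the critical value
$0.95\sqrt{n} + 0.2$ — note that with fewer than ~15 values a single
dominant gap cannot exceed that threshold, a property of the published
procedure itself, so coordinate/covariate screening is only informative for
reasonably sized tables.

## Limitations

Planar-degree geometry is only appropriate near the equator. The bootstrap
correction standardizes sample size, not sampling *design*: systematically
biased collecting within a cell's neighborhood remains invisible. DAPC
memberships overstate certainty relative to admixture models when clusters
are weakly separated. The Nei individual-level distance uses mean-imputed
dosages, which shrinks distances for individuals with much missing data.
And the k suggestion is a heuristic over a heuristic (k-means + BIC): the
scan exists to be looked at, not to be believed blindly.
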