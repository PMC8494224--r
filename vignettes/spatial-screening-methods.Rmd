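---
title: "Density-agnostic spatial screening: models, parameters and design choices"
author: "SpatialScreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-agnostic spatial screening: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
suppressMessages(library(SpatialScreen))
```

# The problem

Spatially resolved transcriptomics assays measure expression together with
the position of every cell, spot or bead. Two recurring analysis questions
are (i) which genes vary in space more than chance placement would explain,
and (ii) whether such variation reflects coordinated structure: shared
spatial programs across genes, putative short-range signaling between cell
types, or spatially distinct subpopulations inside one transcriptional
cluster.

Cell density itself varies across tissue. Any statistic built on Euclidean
distances conflates density with expression pattern: in dense regions,
random expression looks aggregated simply because the cells are close. This
package therefore encodes space only through a *binary neighbor graph*: two
cells are neighbors iff their Voronoi cells touch, i.e. iff they share an
edge of the Delaunay triangulation of the positions (2D or 3D). All
statistics are functions of that graph, never of raw distances — the one
exception being an optional pruning step that removes biologically
implausible long edges before analysis.

# Global statistic: Moran's I with analytic null moments

For a gene with normalized expression $x$ over $N$ cells and binary
symmetric weights $W$ (total weight $W_\Sigma = \sum_{ij} W_{ij}$),

$$ I \;=\; \frac{N}{W_\Sigma}\,
   \frac{\sum_{ij} W_{ij}(x_i-\bar x)(x_j-\bar x)}
        {\sum_i (x_i-\bar x)^2}. $$

The null model is randomization: every assignment of the observed values to
the positions is equally likely. Under it $E(I) = -1/(N-1)$ and the
variance has the closed Cliff–Ord form built from the graph constants
$S_1 = \tfrac12\sum_{ij}(W_{ij}+W_{ji})^2$,
$S_2 = \sum_i (W_{i\cdot}+W_{\cdot i})^2$, the sample kurtosis $S_3$ of
$x$, and $S_4, S_5$ as returned by `moranMoments()`:

$$ \mathrm{Var}(I) = \frac{N S_4 - S_3 S_5}
  {(N-1)(N-2)(N-3)\,W_\Sigma^2} - E(I)^2 . $$

The sign between the two numerator terms is a minus; the test suite checks
the implemented variance against a $10^5$-shuffle permutation estimate and
they agree within Monte-Carlo error, which settles the form empirically.
`moranTest()` reports $z = (I - E(I))/\sqrt{\mathrm{Var}(I)}$ and a
one-sided upper-tail normal p-value — the screen targets positive spatial
autocorrelation; `alternative = "two.sided"` is available. BH adjustment is
applied across all genes of a run.

**Accuracy of the normal tail.** The exact randomization distribution of
$I$ is mildly right-skewed (skewness ≈ +0.16 on a 200-cell Delaunay
graph), so the normal closed form is accurate to roughly ±0.015 in the
mid-range of p and to much better than 0.005 below p ≈ 0.2, the region
that drives discovery decisions. Users who need exact mid-range p-values —
or whose data-generating mechanism violates the randomization null, e.g.
spatially segregated batches — should use `moranPermutationTest()`, which
is the package's Monte-Carlo reference with the $(r+1)/(n+1)$ convention.

Genes without any expression variability are omitted (the statistic is
undefined for them); `dropInvariantGenes()` makes the same guard explicit
in preprocessing.

# Local statistic: LISA, driving fraction, signed scores

Each cell's contribution to the global statistic is

$$ I_i = \frac{N\,(x_i-\bar x)\sum_j W_{ij}(x_j - \bar x)}
             {\sum_i (x_i-\bar x)^2},
   \qquad \sum_i I_i = W_\Sigma\, I .$$

The decomposition identity (asserted at $10^{-10}$ relative tolerance in
the tests) is stated here with the $W_\Sigma$ factor: for binary,
non-row-normalized weights this is the algebraically exact relation; the
commonly quoted $I = \sum_i I_i / N$ holds only for row-standardized
weights where $W_\Sigma = N$.

The *scale* of a pattern is summarized by the **driving fraction**: the
proportion of cells whose $I_i$ is individually significant at
`alpha = 0.05`. A spatially heterogeneous gene is retained by
`selectSpatialGenes()` only if its BH-adjusted global p-value is below
0.05 *and* its driving fraction strictly exceeds 0.05 — the second filter
rejects patterns carried by a handful of outlier cells.

Two per-cell null models are implemented:

* `null = "conditional"` (default): the cell's own value is held fixed and
  the remaining $N-1$ values are permuted over the other positions. The
  neighbor sum is then a sum of $\deg_i$ draws without replacement from the
  leave-one-out population, giving exact first and second moments. This
  flavor is calibrated per cell (each cell rejects at the nominal rate
  under its own null).
* `null = "randomization"`: the classical total-randomization moments, in
  which the cell's own value is exchangeable too. Because the statistic is
  a product of the cell's deviation and its neighborhood's deviation, this
  null only flags cells where *both* factors are jointly extreme, making it
  noticeably more conservative toward isolated spikes.

Both sets of moments are validated against their respective permutation
oracles in the test suite. The per-cell normal approximation is coarse —
the neighbor sum has only $\deg_i \approx 6$ terms — so per-cell p-values
are accurate to a few percent, which is sufficient for the fraction they
feed; they are deliberately not multiplicity-corrected because they never
support per-cell discovery claims.

**Behavior of the hotspot guard under background noise.** When a gene is
pure noise except for ~3 adjacent spiked cells, its driving fraction is the
spike contribution (~1% at $N = 300$) *plus* the per-cell false-positive
rate of the background (~4–5% for a calibrated test). The observed driving
fractions therefore straddle the 5% threshold rather than sitting at 1%,
and the filter suppresses — but does not always zero — such artifacts; the
global BH filter removes most of the rest. With a noiseless background the
driving fraction is exactly the spike fraction and the guard is absolute.
This is an intrinsic property of any calibrated local test, worth knowing
when interpreting genes near the threshold; the conservative
`null = "randomization"` flavor roughly triples the guard's stringency in
the simulations shipped with the tests.

`signedLisa()` returns $\mathrm{sign}(x_i-\bar x)\, I_i$ for display,
with $\mathrm{sign}(0) = 0$ for cells sitting exactly at the mean.

# Pattern grouping via spatial cross-correlation

For two genes $x, y$ the spatial cross-correlation index is

$$ \mathrm{SCI}(x,y) = \frac{N}{2 W_\Sigma}
   \frac{\sum_{ij} W_{ij}(x_i-\bar x)(y_j-\bar y)}
        {\sqrt{\sum_i (x_i-\bar x)^2 \sum_j (y_j-\bar y)^2}} , $$

so that $\mathrm{SCI}(x,x) = I(x)/2$. Only relative values matter
downstream — the matrix feeds a clustering — so the global normalization
constant is immaterial; it is documented here because other conventions
differ by a factor of 2. `spatialCrossCorMatrix()` computes all pairs with
one sparse product and is bit-identical to the pairwise loop.

Genes are grouped by average-linkage hierarchical clustering on the
dissimilarity $d = \max(\mathrm{SCI}) - \mathrm{SCI}$ (a nonnegative,
order-preserving transform; both the transform and the linkage are
arguments of record). The dendrogram is cut adaptively: flat cuts at
$k = 2,\dots,$ `kMax` are scored by mean silhouette width on the same
dissimilarity, the best cut wins, and groups smaller than
`minPatternSize = 5` genes are moved to pattern 0 ("unassigned"). This
height-based adaptive cut is deterministic and invariant to gene input
order; it recovers three planted orthogonal pattern modules with adjusted
Rand index 1 in the shipped simulations. Pattern summaries Z-score each
member gene across cells and average (`summarizePatterns()`), and
`interpolatePattern()` renders a summary onto a regular grid with a
C0/C1 scattered-data interpolant (`interp`), masking everything outside
the convex hull; interpolation is a display device only and no statistic
consumes it.

# Cell–cell communication: inter-cell-type cross-correlation

For a receptor expressed by the $N$ cells of type A and a ligand by the
$M$ cells of type B, adjacency is restricted to the rectangular inter-type
block $W^{ict}$ (`interTypeAdjacency()`), and

$$ \mathrm{iSCI} = \frac{N+M}{2 \sum_{ij} W^{ict}_{ij}}
   \frac{\sum_{i \in A}\sum_{j \in B} W^{ict}_{ij}
         (x_i-\bar x)(y_j-\bar y)}
        {\sqrt{\sum_A (x_i-\bar x)^2 \sum_B (y_j-\bar y)^2}} $$

with means taken within type. Row indices run over type-A cells and column
indices over type-B cells, consistent with the variance terms. Since
within-type edges never enter, the statistic captures only cross-type
spatial complementarity.

Significance comes from a random-label permutation null: each shuffle
permutes the receptor values across A cells and the ligand values across B
cells, holding positions and $W^{ict}$ fixed (shuffling one side only is an
option). p-values use the $(r+1)/(n+1)$ convention, never exactly zero, as
BH requires. The **adaptive ladder** starts at 100 shuffles and multiplies
the budget by 10 with a fresh derived seed whenever no permuted statistic
reaches the observed one, up to a configurable cap of 10,000 — so only
promising pairs pay for precise p-values, and significance calls agree
with a fixed 10,000-shuffle budget on ≥95% of simulated pairs. Results are
a pure function of the seed; no parallel scheduling enters the draws.
`screenPairs()` applies the detection filter per population (value > 0 in
strictly more than `minCells = 30` cells, a deliberately strict
inequality), computes iSCI + adaptive p per surviving pair, and
BH-adjusts within the screen. Direction is explicit
(`"AB"` = receptor in type A) and the two directions are separate screens.

The permutation null tests *exchangeability*. A pair whose two genes are
each spatially patterned but independently so violates exchangeability
without any communication, and the test can reject for it; this is a known
limitation of random-label nulls, and the reason the shipped null
simulations use spatially unstructured genes. Interpreting hits therefore
requires the companion evidence the pipeline provides (per-gene spatial
heterogeneity calls, pattern membership), not the screen p-value alone.

# Spatially informed clustering

`knnExpressionGraph()` builds the usual transcriptional graph: PCA
(centering only — CPM/volume normalization already equalizes technical
scale; `nPcs = 30`, `k = 30` defaults, both recorded on the graph), then
an undirected kNN graph under the union rule. `spatialEdgeWeights()`
re-weights every edge by the *hop-count geodesic* $d$ on the spatial
graph:

$$ w = \frac{1}{d + \alpha} + \beta, \qquad \alpha = \beta = 1 . $$

$\alpha$ bounds the weight of very close pairs (maximum $1/\alpha + \beta$),
$\beta$ is a uniform floor reached in the $d \to \infty$ limit, which is
also the weight assigned to spatially unreachable pairs — disconnected
components are never torn apart by the weighting itself. This
parenthesization is the one in which $\alpha$ actually performs its
guarding role; the literal reading $(1/d + \alpha) + \beta$ is available
behind `literal = TRUE`. `louvainCluster()` then optimizes modularity
(deterministic given its seed; any modularity optimizer would do, and the
igraph Louvain implementation is used).

The two-island demonstration shipped with the tests uses transcriptionally
identical cells on two spatially disconnected islands with a *complete*
transcriptional graph ($k = N-1$): when cells are transcriptionally
indistinguishable, any smaller $k$ merely subsamples noise, while the
complete graph states "no transcriptional preference" exactly. There the
unweighted partition is a single merged cluster and the weighted partition
recovers the islands with adjusted Rand index 1. Because spatially distinct
need not mean biologically distinct, `validateSplitDE()` runs a rank-based
(Wilcoxon) per-gene comparison with BH correction between the two children
of any split as a guardrail: identical children produce ~5% raw rejections
and none after BH in the null simulations.

# Geometry details

* **Pruning.** `prune = "auto"` removes Delaunay edges longer than
  Q3 + 1.5 IQR of the edge-length distribution — a scale-free outlier rule
  requiring no unit choice; the threshold is recorded in the object's
  metadata and cells left isolated are flagged. Pruning always happens
  after triangulation, in 2D and 3D alike.
* **Degenerate inputs.** Duplicate coordinates are rejected (the Voronoi
  diagram is undefined) unless deterministic jitter is enabled
  (`jitter = TRUE`, magnitude $10^{-9}$ of the bounding-box diagonal,
  seed recorded). Grid-like cocircular inputs without jitter may differ
  across platforms in their choice of quadrilateral diagonals. Collinear /
  coplanar inputs fail with a geometric error.
* **3D.** The 3D triangulation is an in-package incremental
  Bowyer–Watson tetrahedralization (Rcpp); 2D uses `deldir`. Both are
  checked edge-for-edge against a brute-force empty-circumcircle /
  circumsphere oracle on dozens of random point sets.
* **Serial sections.** When section spacing dwarfs in-plane distances,
  `crossSectionAdjacency()` links consecutive sections by mutual k-nearest
  neighbors in the (x, y) plane (`k = 6` by default — small enough to keep
  pairing local, large enough to tolerate section-to-section jitter);
  mutuality makes the relation symmetric by construction.
* **Distances.** Every downstream use of spatial distance is the hop count
  on the graph (`geodesicDistances()`), preserving density-agnosticism.

# Preprocessing

Sequencing-based counts get counts-per-million without log transformation
(`normalizeCPM()`); segmentation-based imaging counts are divided by each
cell's imaged volume (`normalizeVolume()`). Both preserve zeros and
within-cell rank order exactly. A normalization record on the
`SpatialExpressionSet` container warns on double normalization but does
not refuse — data arriving pre-normalized is common and remains the
caller's responsibility. One practical caveat the package's own examples
surface: with very small gene panels, CPM couples genes through the cell
total, so spatial structure in a few strong genes induces compensatory
(anti-correlated) structure in the rest; panels in realistic use are large
enough for this compositional effect to be negligible.

# What the synthetic data emulate — and what they do not

The generators (`simulatePositions()`, `simulateNullGenes()`,
`simulatePatternGenes()`, `simulateCommunication()`,
`simulateSplitClusters()`) are first-class, seeded, pure functions that
reproduce the statistical structure the methods target: uniform and
density-skewed point processes, a monotone coordinate warp
($x \mapsto x^\gamma$, default $\gamma = 2$) for density-robustness
studies, linear gradients, Gaussian bumps, sinusoidal stripes (with an
anti-phase variant), hyperplane splits, tiny 3-cell spikes at +5 noise sd
for the hotspot guard, interleaved two-type layouts with one planted
communicating pair, and two-island split-cluster scenarios. Default noise
is Gaussian with sd 1 (so `effect` is a signal-to-noise ratio); a Poisson
mode with log-normal library-size factors (sd 0.3, mean 5 counts) feeds
end-to-end tests through CPM. Pattern modules used in grouping tests share
one surface per module and are placed on orthogonal axes so the planted
patterns are genuinely disjoint.

These fixtures do not emulate real-data features such as gene–gene
correlation beyond the planted structure, zero inflation, segmentation
errors, batch or section effects, or realistic gene-panel compositions.
Passing tests therefore demonstrate correctness of the statistics and the
advertised robustness properties under controlled conditions — not
biological performance on any particular platform.

Problem sizes in the shipped tests and in `scripts/acceptance.R` (100–1000
cells, 50–1100 genes, up to $10^5$ shuffles) were chosen so the full suite
reruns from scratch in a few minutes on a single core while keeping every
Monte-Carlo comparison inside its stated error bands.

# Known limitations

* Normal-tail p-values for both the global and the local statistic carry
  the approximation error quantified above; the permutation paths are the
  references when that matters.
* The hotspot guard is a strong attenuator, not an absolute filter, when
  the background itself is noisy (see the LISA section).
* The communication null tests exchangeability, not communication per se.
* Inference is proximity-based by construction: only short-range,
  neighbor-graph-mediated relations are visible.
* The pattern count chosen by the silhouette-guided cut is a heuristic; the
  dendrogram is returned so users can cut differently.
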