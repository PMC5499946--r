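---
title: "Cellular connectivity networks of whole organs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cellular connectivity networks of whole organs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organtopo)
```

## The model

An organ is represented as an undirected graph: one node per cell, one
edge per shared wall between two cells, with the wall area in µm² as the
edge attribute. This abstraction assumes that (i) cell-to-cell transport
and mechanical coupling act across shared walls, so the interface graph
is the natural substrate for organ-scale communication; (ii) the
segmentation is watertight enough that face adjacency of labeled voxel
regions identifies real walls; and (iii) interface area is a meaningful
edge weight (larger wall, stronger potential coupling).

Three normalized centralities summarize each cell's role. Degree counts
interface partners. Node betweenness centrality sums, over all unordered
cell pairs, the fraction of tied shortest paths through the cell and is
normalized by `2/((N−1)(N−2))` so that the hub of a star equals 1
regardless of organ size; edge betweenness is normalized by
`2/(N(N−1))`. Shortest paths are hop counts by default; the weighted
variant uses `1/area` as the edge length, making routes through large
interfaces "shorter". Ties among equal-length paths are handled by
standard fractional counting, and no further normalization (e.g. by
network density) is applied beyond the stated pair-count factors. A
current-flow (random-walk) edge betweenness is provided as a separate,
clearly named measure: it treats the network as a resistor network (unit
conductances) and measures the mean absolute current an edge carries
over all source–sink pairs, computed from the Moore–Penrose
pseudoinverse of the graph Laplacian. On trees it coincides with the
shortest-path edge measure; elsewhere it rewards edges on *all* short
routes, not only the geodesics.

Cut boundaries distort topology: cells at the sample ends lose
neighbors, and their centralities are biased. The package therefore
computes every centrality on the *full* graph but reports statistics
only for cells farther than a buffer (default 2 graph hops) from any
flagged boundary cell. Buffering by masking is deliberately different
from deleting boundary cells before the computation — deletion changes
the retained cells' values, which a test in the suite asserts
explicitly. Vascular cells likewise stay in every computation but are
excluded from reported per-cell statistics, because their segmentation
is unreliable in practice. Whether a buffer should be defined in graph
hops or in axial distance is genuinely open; hops were chosen because
they are available for edge-list inputs that carry no coordinates.

Interfaces smaller than 2 µm² are treated as segmentation artifacts and
removed before analysis — strictly `< 2`, so an exactly-2 µm² wall is
retained — except when either endpoint is vascular, since thin vascular
interfaces are genuine. The vasculature exemption is read as applying to
any vasculature-incident edge.

## Distribution statistics

Degree is discrete, so two groups are compared by a chi-squared
homogeneity test on the pooled contingency table over observed degree
values; categories with expected counts below 5 are merged into their
neighbor to keep the test valid. Betweenness is continuous and heavily
right-skewed, so groups are compared by the two-sample
Kolmogorov–Smirnov test on raw values; log10 transformation is applied
only where means and standard deviations are summarized (zero-BC cells
are excluded from the transformed set rather than pseudo-counted,
because no principled pseudo-value exists). Cells are pooled across the
three biological replicates of a group before testing; pooling matches
the "distribution comparison" framing and maximizes power. The
family-wise error rate is controlled by Bonferroni correction with
m = 3200 comparisons as the study-wide default, giving the working
threshold `0.05/3200 = 1.5625e-5`.

Robustness across replicates is quantified by the coefficient of
variation (sd divided by the absolute mean, so that the all-negative
log10 BC values yield a nonnegative CV) of log10 BC per replicate,
followed by one-way ANOVA across groups and Tukey's HSD; a group is
"distinct" when it differs from every other group at the stated level.

Mutual information between per-cell features uses the estimator
appropriate to each pair: Kraskov–Stögbauer–Grassberger (algorithm 1,
Chebyshev metric, strict marginal counts) for continuous–continuous
pairs, the Ross kNN estimator for discrete–continuous pairs, and
plug-in entropy sums for discrete–discrete pairs, all reported in bits.
k = 3 neighbors is the customary default and is configurable. kNN
estimates around zero are noisy and may be slightly negative; they are
reported as-is (a floor-at-zero option exists) because silent clipping
hides estimator bias. Discrete classes observed only once are dropped
before estimation, as their neighborhoods are undefined. The estimators
assume continuous variables have no heavy ties; degree is never fed to
the continuous estimators.

Group similarity matrices use the *test statistic* (chi-squared value or
KS D) as the distance between two distributions, and groups are
clustered by average-linkage (UPGMA) agglomeration on that precomputed
matrix, cut at k = 3 by default, with Newick export of the dendrogram.
The statistic, not its inverse, is the distance: similar groups have
small statistics and must be near each other. A `transform = "inverse"`
switch reproduces the alternative literal reading, in which zero
statistics are mapped to a large finite cap. These matrices are
symmetric with zero diagonal but are not metrics, which average-linkage
tolerates.

## Tracer transport

Per-cell tracer concentration is the summed voxel signal over the
cell's physical volume (signal·µm⁻³) — the "volume and internal signal"
reading of heat-map quantification. Concentrations are mean-normalized
over the pooled comparison set (both epidermal types together, as the
pooled-then-normalized protocol implies), and the epidermal differential
is tested with Welch's t-test at α = 0.001 (a pooled-variance flag
exists for exact reproduction attempts). Fewer than 40 cells per type
triggers a warning, mirroring the usual protocol floor. The suite
verifies exact signal conservation: concentrations times volumes sum to
the total labeled signal to 1e-9 relative.

## The synthetic organ generator

The generator emulates a radially symmetric hypocotyl: concentric rings
(vascular core, endodermis, inner and outer cortex, epidermis) of
circumferential cell files, each file a column of cells along the axis.
The epidermal ring alternates trichoblast and atrichoblast files, with
each trichoblast file centered over the junction of two cortical files
(radial contacts with both) and each atrichoblast file strictly over one
— reproducing the hair-cell bridging rule that gives trichoblasts their
higher degree. Adjacent rings are angularly staggered so sector
boundaries never coincide, which keeps the rasterization's face
adjacency identical to the generated graph. Interface areas are drawn
lognormal per layer-pair class with defaults ordered cortex > epidermis
> vasculature (means 400–420, 200, 60 µm², CV 0.3–0.35); these are free
parameters, not calibrated to any particular dataset. Cell wall area
and volume come from the cylindrical sector geometry with multiplicative
lognormal size jitter (CV 0.15), which couples area to volume but leaves
topology independent of size — so the MI panel finds MI(area, volume)
high and MI(area, BC) low, the qualitative pattern expected when path
length is not a cell-size effect.

Three sources of structural randomness make replicate organs
topologically distinct and their betweenness distributions diffuse,
as in real tissue:

* per-file axial phases and per-wall jitter (quarter-cell quanta, so
  the rasterizer reproduces them exactly): files do not line up, and
  individual walls stagger;
* junction contact wobble (`contact_wobble_q`, default 0.35): a cell
  whose angular footprint nearly reaches a neighboring file of the
  adjacent ring (within half its own width) gains a genuine contact
  with that probability. Real 3D packings are full of such grazing
  contacts, which is why measured hypocotyl degrees are far noisier
  than any clean lattice; wobble also softens the atrichoblasts'
  radial-contact deficit without erasing the bridging-driven degree
  differential;
* optional per-file axial-count variation (`n_axial_cv`, default 0):
  off by default because coherent per-file variation makes pooled
  two-sample tests anti-conservative (whole files move together), a
  property worth demonstrating deliberately rather than building into
  the default conditions.

The default organ has 5 rings × 40 axial cells (1760 cells, ≈ 11000
interfaces, 2000 µm long); a ~220-cell toy preset supports fast tests.
Both presets place the epidermis at twice the outer-cortex file count,
the only arrangement that tiles the bridging rule, and the constructor
rejects counts that cannot tile.

**Conduit mode.** The organ's epidermis can be switched into a state
where atrichoblast files carry half as many (hence twice as long) cells
as trichoblast files. Long-range paths along the organ then need fewer
hops through atrichoblast files, which concentrates shortest paths
there and makes the atrichoblast betweenness distribution
stochastically larger — a hop-count mechanism for a low-path-length
"conduit" cell file. The anatomical cause of reduced path length in
real organs is unknown (cell length, file continuity and junction
geometry are all candidates); cell length was chosen as the most
parsimonious knob. Two consequences are worth stating plainly. First,
with equal epidermal cell lengths (conduit off), the trichoblast and
atrichoblast BC distributions overlap enough that the pooled KS test at
the Bonferroni threshold stays non-significant, while the degree
differential remains — the configuration of a wild type without the
conduit property. Second, cells twice as long necessarily gain
circumferential and radial contacts, so in conduit mode the
atrichoblast *degree* overtakes the trichoblast degree; the length-based
mechanism cannot reproduce the degree differential and the BC
differential simultaneously. Degree-differential checks therefore run
on equal-length organs. This is a known limitation of the generator,
not of the analysis code.

Artifact injection adds `round(rate × edges)` spurious contacts between
random non-adjacent, non-vascular cell pairs with areas uniform below
2 µm², emulating image-processing artifacts; the standard filter
removes exactly these, which the suite asserts as set equality.

What the generator does **not** emulate: growth and biomechanics, real
ecotype geometry, curved or tapering organs, air spaces, and
segmentation errors other than the thin-interface artifact class.
Passing tests on synthetic organs show the pipeline recovers known
structure under these idealized conditions; they cannot certify
performance on volumes whose artifacts fall outside that class.
Wobble contacts exist only in the generated graph — a rasterized volume
contains the lattice geometry only — so volume-based tests use
`contact_wobble_q = 0`.

## Numerical choices and degenerate inputs

Betweenness normalization requires N ≥ 3 (nodes) or N ≥ 2 (edges);
smaller graphs are rejected. Disconnected inputs are computed per
component with the whole-graph N kept in the normalization (matching
the stated formulas) and a warning. Zero-area edges are rejected before
weighting. Interval overlaps in the generator use a 1e-9 tolerance in
axial fractions and angular turns; all stochastic layout quantities are
quantized (quarter-cell phases, half-width wobble threshold) so that
overlap decisions are never made on floating-point slivers. The KS test
uses the asymptotic p-value (ties in pooled BC values make exact
p-values unavailable); the chi-squared test uses no continuity
correction, matching the textbook Σ(O−E)²/E statistic that the test
suite verifies directly. Identical constant groups yield a 0/0
chi-squared statistic, reported as statistic 0, p 1. Category merging
in degree tables can collapse everything into one category for tiny
near-constant samples; `compare_degree` then errors, and the pipeline
records an NA comparison row rather than aborting the run.

Randomness is driven by one integer seed per organ spec; replicate r of
a run uses `seed + r − 1`, and the generator derives independent
sub-streams for layout, attributes and artifact placement by fixed
offsets, so toggling one randomness source never shifts another.
`run_pipeline` is byte-deterministic given its configuration.

## Problem sizes used by the test suite

Oracle equivalence runs 200 random connected graphs of 5–30 nodes
against a brute-force path-enumeration oracle (tolerance 1e-12) and 100
random labeled arrays of up to 1000 voxels against a naive face-scan
oracle (exact). Conduit recovery uses 20 three-replicate batches of the
default 1760-cell organ per mode; statistical calibration uses 1000
simulated null pairs per test. The MI anchors use n = 10⁴ (correlated
Gaussian, ±0.05 bits) and exact plug-in identities. These sizes were
chosen to exercise the asymptotic regimes the methods rely on while
remaining comfortably desk-scale.

## Known limitations

* The conduit mechanism is one plausible choice among several; its
  degree side-effect is documented above.
* Interface-area distributions are qualitative (ordered means, lognormal
  shape), not calibrated to measured wall areas.
* The Ross estimator drops singleton discrete classes; for samples
  dominated by unique degree values the discrete–continuous MI is
  undefined and the pipeline skips that cell type.
* Edge-list inputs carry no geometry, so the MI panel (which needs cell
  area and volume) is skipped for them.
* Hop-based buffering may under- or over-trim organs whose cells vary
  strongly in length near the cut.
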