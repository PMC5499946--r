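# organtopo

Topological analysis of whole-organ cellular connectivity networks.

Every cell in a plant organ touches its neighbors across shared walls.
Treating cells as nodes and shared-wall interfaces as edges (weighted by
wall area in µm²) turns an entire organ into a network whose global
structure can be interrogated: which cell types are local hubs, which lie
on the short paths that long-range molecular movement must use, and how
reproducible that architecture is across individuals, genotypes and
species. `organtopo` implements this analysis for radially organized
organs such as the seedling hypocotyl, where the epidermis splits into
hair (trichoblast) and non-hair (atrichoblast) cell files and the
interior is a stack of concentric rings (cortex layers, endodermis,
vascular core).

The package is aimed at quantitative plant biologists with labeled 3D
segmentations (or MorphoGraphX-style edge-list exports) in hand, and at
methodologists who want a controllable synthetic organ to probe what
network statistics can and cannot detect.

## What it computes

For a network with `N` cells:

* **degree** — the number of interface partners of a cell;
* **node betweenness centrality** `BC(v) = Σ_{s<t} σ_st(v)/σ_st ·
  2/((N−1)(N−2))` over unweighted shortest paths, so `BC ∈ [0,1]`;
* **weighted BC** — identical normalization, but paths minimize the
  summed reciprocal wall area (`length(e) = 1/area µm²`), so large
  interfaces act as short steps;
* **edge betweenness** normalized by `2/(N(N−1))`, plus a current-flow
  (random-walk) variant computed from the graph Laplacian;
* distribution machinery: chi-squared comparison of degree
  distributions, two-sample Kolmogorov–Smirnov comparison of BC
  distributions, Bonferroni control (`0.05/3200 = 1.5625e-5` by
  default), coefficient-of-variation robustness analysis with
  ANOVA + Tukey HSD;
* **mutual information** in bits between per-cell geometry (wall area,
  volume) and topology (degree, BC), using Kraskov–Stögbauer–
  Grassberger and Ross kNN estimators (Rcpp) and plug-in entropy for
  discrete pairs;
* hierarchical clustering of groups from test-statistic distance
  matrices, with Newick dendrogram export;
* per-cell tracer (e.g. fluorescein) concentration from a labeled
  volume plus signal channel, mean-normalized and compared between
  epidermal types by t-test.

Networks are built from labeled volumes by 6-connected face scanning
(`extract_adjacency`), cleaned by removing interfaces below 2 µm²
(vasculature-incident interfaces exempt), and buffered: cells near the
sample cut participate in every centrality computation but are excluded
from reported statistics.

A fully parametric generator (`organ_spec`, `generate_organ`,
`rasterize_organ`, `generate_signal_volume`, `inject_artifacts`) builds
hypocotyl-like cylinders — with trichoblast files bridging two cortical
files, staggered cell walls, junction contact wobble, and an optional
"conduit" mode in which atrichoblast files carry half as many, twice as
long cells — so every stage of the pipeline is testable without
microscopy data.

## Worked example

```r
library(organtopo)

g <- generate_organ(default_organ_spec(seed = 1))
g
#> <cell_graph> 1760 cells, 10842 interfaces
#>   cell types: atrichoblast=320, endodermis=320, inner_cortex=320,
#>               outer_cortex=320, trichoblast=320, vasculature=160

g <- filter_small_interfaces(g, 2.0)   # imaging-artifact filter
g <- mark_buffer(g, depth = 2)         # flag boundary-adjacent cells
mt <- measure_topology(g, c("degree", "bc"))
central <- report_central(mt$nodes)    # central, non-vascular cells

aggregate(cbind(degree, bc) ~ cell_type, central, mean)
#>      cell_type degree      bc
#> 1 atrichoblast   8.51 0.00399
#> 2   endodermis  13.43 0.00709
#> 3 inner_cortex  14.75 0.01296
#> 4 outer_cortex  16.78 0.01553
#> 5  trichoblast   9.05 0.00474
```

Interior layers out-connect the surface (they face more rings), and
trichoblasts out-connect atrichoblasts because each trichoblast file
bridges two underlying cortical files:

```r
compare_degree(central$degree[central$cell_type == "trichoblast"],
               central$degree[central$cell_type == "atrichoblast"])
#>          test statistic   p_value significant
#> 1 chi_squared     24.39 0.0004429       FALSE
```

A single organ is suggestive but does not clear the study-wide
Bonferroni threshold (`1.5625e-5`); pooling three replicate organs, as
`run_pipeline()` does, yields a chi-squared statistic near 69 and a
clearly significant differential. The same pipeline run with
`conduit_mode = TRUE` makes the atrichoblast BC distribution
stochastically larger (KS `D ≈ 0.99`) — the signature of a low-path-
length conduit cell file — while the KS comparison stays non-significant
in the matched no-conduit organs.

The one-call orchestration:

```r
cfg <- run_config(input = "synthetic", conduit_mode = TRUE, seed = 1)
res <- run_pipeline(cfg, out_dir = "out")   # measures.csv, comparisons.csv,
                                            # mi.csv, clusters.csv,
                                            # dendrogram.nwk, log.txt
```

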