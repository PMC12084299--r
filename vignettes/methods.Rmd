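---
title: "Methods: spatial single-cell analysis of multiplexed tissue images"
author: "imcniche"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial single-cell analysis of multiplexed tissue images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The analysis this package implements

Imaging mass cytometry (IMC) records ~20-40 antibody channels at ~1 µm
resolution over rectangular regions of interest (ROIs) of a tissue
section. After cell segmentation (external to this package; we consume
label masks), each cell is a point in space with a marker-expression
vector, and the scientific questions are compositional and spatial: which
cell populations are present, how are they organised into local
neighbourhoods, and which type pairs sit together or apart more than
chance allows. The motivating application is the labial salivary gland
in primary Sjögren's syndrome (pSS), where lymphocytic infiltration —
CD8+ T cells in particular — reorganises a predominantly epithelial
tissue; the package is written so that any multiplexed-imaging cohort
with two or more clinical groups fits the same interfaces.

The pipeline stages, each an exported function over
`SingleCellExperiment` / S4 containers:

1. **Preprocessing** (`compensateSpillover`, `denoiseMedian`,
   `adjustIntensityLinear`): per-pixel non-negative unmixing of channel
   spillover, 2-D median denoising, and linear contrast adjustment. The
   order is fixed: spillover → median → adjustment → quantification.
2. **Quantification** (`quantifyCells`): mean channel intensity, centroid
   and area per mask label.
3. **Phenotyping** (`normalizePercentile`, `clusterExpression`,
   `annotateClusters`): range normalization to the 99th percentile per
   marker over all cells; a shared-nearest-neighbour graph clustering
   (kNN in expression space, Jaccard edge weights, Louvain communities);
   ordered marker-gating rules that name each cluster, with a
   "mixed immune" fallback when a cluster carries more than one immune
   lineage signal and "unassigned" when it carries none.
4. **Cellular neighbourhoods** (`spatialKnn`, `neighborhoodProfiles`,
   `clusterNeighborhoods`, `annotateCNs`): per cell, the CN window is
   the cell plus its 20 nearest neighbours within the same ROI; the
   window's cell-type fraction vector is its profile; k-means (k = 10,
   Euclidean) over all profiles defines the CN vocabulary, and each CN
   is labelled by the types enriched ≥ 1.5× over the global composition.
5. **Interaction statistics** (`countInteractions`, `testInteractions`,
   `compareInteractionsGroups`, `densityQuartileAssociation`,
   `compositionCorrelation`): the directed interaction count of (A → B)
   in an ROI is the mean, over A cells, of the number of B cells in
   their CN window. Significance comes from a within-ROI label
   permutation null; group differences from Welch t tests on per-ROI
   counts; infiltration-density associations from equal-size rank
   quartiles of images; compositional couplings from per-ROI fraction
   correlations.
6. **Reporting** (`runPipeline`, `renderVoronoi`,
   `renderSummaryFigures`): orchestration from a YAML config, stage
   tables as CSV, a manifest with checksums, and figure analogs
   (cluster × marker heatmap, stacked compositions, CN abundance,
   directed interaction heatmap, Voronoi maps).

# The permutation test

For each ROI, cell positions and the kNN graph are held fixed and the
type labels are shuffled uniformly `nPerm` times (default 1000; the
label multiset is preserved exactly, so per-type abundances never
change). For an ordered pair the enrichment p-value uses the add-one
estimator `(1 + #{perm ≥ obs}) / (nPerm + 1)`, its avoidance twin uses
`≤`, and a pair is called an interaction (avoidance) when the
corresponding p falls below α = 0.05. The add-one form keeps p ≥
1/(nPerm+1), makes the null distribution super-uniform, and avoids
p = 0. Counts are directed — (A → B) measures the composition of A's
neighbourhoods, which need not equal (B → A) — matching the asymmetric
interaction heatmaps such analyses report. Within-ROI shuffling is the
only permutation scope offered: pooling labels across ROIs would
confound composition differences between acquisitions with spatial
structure inside them.

# The synthetic-tissue generator

No clinical IMC data ships with this package, so every stage is
validated against a simulator whose ground truth is known by
construction (`CohortSpec`, `generateROI`, `generateCohort`):

- **Design**: groups × samples × ROIs, each ROI an independent
  400 × 400 px window with Poisson(500) cells by default.
- **Placement**: unstructured types are uniform (homogeneous Poisson);
  attraction pairs follow a Neyman–Scott scheme (type-B offspring
  scattered uniformly within `clusterRadius` of type-A parents);
  avoidance pairs are proposal-thinned so that no A–B pair lies within
  `exclusionRadius` — an exact hard-core constraint, checked exactly in
  the tests. All placements respect a hard-core 2 × `cellRadius`
  overlap rule via rejection sampling (100 attempts per cell, then an
  explicit packing-failure error naming the ROI).
- **Niches**: an optional rectangle partition of the ROI, each region
  with its own composition; a cell's true niche is recorded.
- **Rendering**: cells are hard discs (radius 3 px) stamped into a
  uint16 label mask, which makes mask-based quantification exactly
  invertible; per-cell marker levels are lognormal draws from a
  (type × marker) table, spread uniformly over the disc, plus a
  constant background (0.05), optional spillover mixing, and per-pixel
  Poisson counting noise.
- **Seeds**: one master seed; each ROI derives its stream seed from a
  hash of (master, sample, roi), so any ROI regenerates identically in
  isolation.

The default composition has two groups whose immune fractions (14.5%
control, 27.6% case) bracket the range reported for low- versus
high-infiltration labial salivary glands; the 12 populations and their
defining markers mirror a typical gland panel (panCK, vimentin, CD31,
aSMA, CD45, CD8a, CD4, FOXP3, CD20, CD56, CD15, CD68, plus functional
and disease markers). The expression model separates populations by
≥ 4 σ on their lineage markers; the "mixed immune" population
deliberately carries two immune signals (CD8a and CD20) so the
annotation fallback is exercised. All of these are synthetic defaults:
no per-type IMC intensity distributions are published for this tissue,
and none of the numbers here are estimates from measured data.

What the simulator does **not** emulate: acquisition physics beyond
spillover and Poisson noise, irregular cell shapes, nucleus/membrane
channel structure, segmentation errors, batch effects, or spatially
varying background. Passing tests therefore demonstrate correctness of
the statistics on point-referenced typed cells with noisy marker
levels — not robustness to segmentation artefacts or staining batch
variation, which real data adds on top.

# Parameter choices and numerical decisions

- **Spillover unmixing** solves `min ‖Sᵀx − o‖², x ≥ 0` per pixel. The
  fast path is the unconstrained linear solve; only pixels with a
  negative component are refined by active-set NNLS
  (`pracma::lsqnonneg`). An ill-conditioned S (condition number > 1e8)
  triggers a warning and the all-NNLS path, which is defined for any S.
  No spillover matrix is ever invented: the default is the identity
  (no-op), and `syntheticSpillover()` is clearly labelled synthetic.
- **Median window** default 3 px; edges handled by mirror reflection
  (implemented in C++ with `std::nth_element`).
- **Linear adjustment** defaults to percentiles (1, 99) computed over
  the whole channel, background included; the low percentile maps to 0,
  the high percentile to its own value, and values outside clip.
  Caveat for sparse masks: when a marker is positive in under 1% of
  *pixels* (as happens in the simulator, whose discs cover ~9% of the
  image), the 99th pixel percentile sits below the positive signal and
  the clip truncates it; the end-to-end analyses in this package's
  validation therefore use (1, 99.9). On dense, confluent tissue the
  default is benign.
- **Normalization** uses the type-7 (linear interpolation) percentile
  pooled over all cells per marker, with clipping to [0, 1]; a marker
  whose percentile is 0 normalizes to all-zeros with a warning rather
  than dividing by zero.
- **Expression clustering**: k = 30 neighbours, Euclidean distance on
  lineage markers only (functional markers would mix activation state
  into phenotype; the marker set is configurable). Jaccard weights are
  computed from the directed kNN sets; communities come from Louvain
  with a fixed seed at resolution 0.05. The low resolution is
  deliberate: well-separated populations occupy (near-)disconnected
  components of the kNN graph, which modularity optimization never
  merges regardless of resolution, while resolution 1 fragments large
  homogeneous populations into spatial micro-clusters. 0.05 recovers
  populations exactly across simulated cohorts; analysts who want
  finer substructure can raise it.
- **Annotation** is a pure function of cluster mean expression and the
  ordered rule list: first match wins among structural rules, more than
  one immune match yields the fallback, no match yields "unassigned"
  (reported, never dropped). The positivity threshold defaults to 0.5
  on the normalized scale and is per-rule configurable.
- **CN window** includes the center cell (window size 21 at k = 20),
  following the usual field definition of a cellular neighbourhood as
  a center cell together with its k nearest neighbours;
  `includeCenter = FALSE` switches to neighbours-only windows.
  Profiles are fractions rather than counts so that edge cells with
  truncated windows remain comparable.
- **CN k-means**: k-means++ seeding, 10 restarts, Lloyd iterations
  capped at 300, best restart by within-cluster sum of squares,
  deterministic under seed; CN ids are size-ordered. Profiles are
  pooled cohort-wide before fitting — a single CN vocabulary is what
  makes cross-group CN-abundance comparisons meaningful; per-group
  fits would need a CN-matching step for which no canonical
  construction exists.
- **Ties and determinism**: kNN ties at the k-th distance break by
  ascending cell index; density ties at quartile boundaries break by
  image id; every stochastic step takes an explicit seed, and the
  pipeline manifest records parameters and table checksums so a rerun
  is verifiably byte-identical.
- **Correlation method**: the composition-correlation analog defaults
  to Pearson (as its figure states) while Spearman is one argument away
  (as the methods text states); the discrepancy in the source is
  documented, not resolved.
- **Group tests**: Wilcoxon rank-sum for composition and CN abundance,
  Welch t for interaction counts; p-values are reported raw at α = 0.05
  with optional Benjamini–Hochberg adjustment behind a flag — raw p at
  a fixed α is the convention in exploratory spatial screens of this
  kind, and the adjustment is one flag away when a confirmatory
  reading is wanted.

# Validation design and problem sizes

The test suite checks every operation against an independent
implementation or a closed form: brute-force kNN, profile recounts and
double-loop interaction counts on ≥ 20 random ROIs; brute-force region
averaging for quantification; percentile and median-filter oracles;
forward-model inversion for spillover. Calibration and power use
simulation at sizes chosen to keep the whole suite within a typical
continuous-integration budget: 400 ROIs of 300 cells (n_perm = 199) for
the type-I-error band of the permutation test; 100 replicate ROIs per
planted-structure scenario.

The two power scenarios are themselves design choices worth recording.
A CN window of 21 cells at the default density integrates over a
~46 px radius, so clustering at 15 px is strongly diluted; the
attraction scenario therefore plants many small parent–offspring
clusters (2 offspring per parent) in a co-dominant two-type
composition (0.35/0.35) on a 600 × 600 px ROI — biologically, many
small periductal aggregates rather than a few large foci. The
avoidance scenario (exclusion 40 px, both types at 0.12) needs no such
care: a 40 px hole in a 46 px window is a large deficit, and placement
remains feasible because the excluded partner occupies only ~12% of
cells. Planting a 40 px exclusion against a majority type would make
hard-core placement itself infeasible — an instructive constraint of
hard-core processes, not a limitation of the test.

# Known limitations

- Segmentation is consumed, never performed; mask quality bounds
  everything downstream.
- Batch alignment (e.g. Harmony) is not reimplemented; the clustering
  accepts an externally corrected matrix through the `markers` /
  assay hooks.
- UMAP embeddings are considered visualization and are out of the core;
  no embedding logic ships.
- The permutation test conditions on composition within each ROI; it
  cannot separate attraction of A to B from joint attraction of both to
  an unmodelled third structure.
- Voronoi maps clip to the ROI rectangle; territory areas at the tissue
  border are underestimates.
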