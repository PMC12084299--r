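# imcniche

Spatial single-cell analysis of multiplexed tissue images (imaging mass
cytometry, IMC) in R/Bioconductor style: per-cell quantification from
segmentation masks, phenotype clustering and annotation,
cellular-neighbourhood (CN) discovery, permutation tests for cell–cell
spatial interaction/avoidance, and group-level association analyses —
plus a ground-truth synthetic-tissue simulator that makes every stage
testable without access to clinical data.

## Who this is for

Groups analysing multiplexed imaging cohorts (IMC, MIBI, CODEX-like
data) of tissues with infiltrating immune populations — the motivating
case is the labial salivary gland in primary Sjögren's syndrome, where
lymphocytic infiltration reorganises a predominantly epithelial tissue —
who need the standard single-cell spatial toolbox behind one set of
tested, seeded, reproducible functions.

## The statistics at the core

**Phenotyping.** Marker expression per cell is range-normalized to the
99th percentile per channel over all cells, then clustered on a
k-nearest-neighbour graph in expression space (Euclidean, k = 30) whose
edges are reweighted by the Jaccard overlap of neighbour sets, with
Louvain community detection. Ordered marker-gating rules map clusters to
populations; a cluster with two immune lineage signals becomes
"mixed immune", one with none stays "unassigned".

**Cellular neighbourhoods.** The CN window of a cell is the cell plus
its 20 nearest neighbours in the same ROI. The window's cell-type
fraction vector is clustered by k-means (k = 10, Euclidean, k-means++
seeding, 10 restarts); each CN is annotated by the types enriched
≥ 1.5× over the global composition.

**Interactions.** The directed count for a type pair (A → B) in an ROI
is the mean over A cells of the number of B cells in their CN window.
Its null distribution comes from shuffling labels within the ROI
(positions fixed, multiset preserved); with `nPerm` permutations,

    p_enrich = (1 + #{perm >= obs}) / (nPerm + 1)

and the avoidance p analogously with ≤. Pairs are classified
interaction / avoidance / ns at α = 0.05. Group differences use Welch
t tests on per-ROI counts; density associations use four equal-size
rank bins of images ("absent/low/medium/high" infiltration) with a
Spearman trend; compositional couplings use per-ROI fraction
correlations (Pearson by default).

## Worked example

Simulate the default two-group cohort (12 ROIs, ~6000 cells, immune
fraction 14.5% in controls vs 27.6% in cases), recover phenotypes, CNs
and a planted interaction:

```r
library(imcniche)

spec  <- CohortSpec(seed = 1L)          # 2 groups x 3 samples x 2 ROIs
sim   <- generateCohort(spec)
cells <- normalizePercentile(sim$cells)
cells <- clusterExpression(cells, k = 30, seed = 1, panel = defaultPanel())
cells <- annotateClusters(cells)

comp <- compositionSummary(cells)
aggregate(fraction ~ cell_type + group, comp$fractions, mean)
#>              cell_type fraction.case fraction.control
#>             epithelial        0.3971          0.53779
#>                 CD8+ T        0.0681          0.03039
#>                      B        0.0400          0.01676
#>           mixed immune        0.0619          0.02502
#>    ...
```

The annotated case tissue carries the planted excess of CD8+ T, B and
mixed immune cells over the control composition (epithelial falls from
54% to 40% of cells). Cellular neighbourhoods from the same cells:

```r
graph <- spatialKnn(cells, k = 20)
prof  <- neighborhoodProfiles(graph, cells)
cn    <- annotateCNs(clusterNeighborhoods(prof, kCn = 10, seed = 1))
cn
#> CNModel: 10 cellular neighbourhoods over 6177 cells
#>   sizes: 745, 716, 688, 650, 598, 584, 583, 556, 556, 501
#>   labels: CN1=aSMA+ fibroblast enriched; CN2=endothelial enriched;
#>           ...; CN6=B, CD8+ T, mixed immune, neutrophil, NK,
#>           resident macrophage enriched; CN8=CD8+ T enriched; ...
```

Mixed immune-enriched CNs (CN5, CN6) emerge without any planted niche —
they are the CN-level signature of the infiltrate. A planted
Neyman–Scott attraction (CD8+ T offspring around epithelial parents,
15 px clusters) is detected by the permutation test:

```r
att <- generateROI(plantedAttractionSpec(seed = 2), "control",
                   render = FALSE)
g   <- spatialKnn(att$cells, k = 20)
res <- testInteractions(g, att$cells, nPerm = 199, seed = 1,
                        typeCol = "true_type")
subset(res, from_type == "epithelial" & to_type == "CD8+ T",
       select = c(observed, null_mean, p_enrich, classification))
#>    observed null_mean p_enrich classification
#> 42 7.048544  6.622445    0.005    interaction
```

Each epithelial cell's 21-cell window holds 7.05 CD8+ T cells against a
permutation-null mean of 6.62 — an excess the label-shuffle null rejects
at p = 0.005.

The full pipeline (preprocessing from images + masks, or a simulated
cohort) runs from a YAML config and writes stage tables, figures and a
checksummed manifest:

```sh
Rscript inst/scripts/run_pipeline.R --config inst/extdata/example_run.yaml
```

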