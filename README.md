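# microglia3d

Fully automated 3D morphometry of microglia from two-channel confocal
Z-stacks.

Microglia — the brain's resident immune cells — shift from a highly
**ramified** shape (small soma, many fine processes) toward an **amoeboid**
shape (compact, few processes) when they activate, for example around an
ischemic lesion. That shape change is one of the most widely used readouts of
microglial activation, yet it is still often quantified by hand: slow,
rater-dependent, and limited to a handful of 2D measures. `microglia3d`
replaces the manual workflow with a deterministic pipeline that takes a
two-channel Z-stack (a membrane/cytoplasm marker such as anti-Iba1, plus a
nuclear stain such as DAPI) and returns **59 morphological features per
cell** together with a single PCA compound score of ramification.

The pipeline has four stages:

1. **Quality control.** Pearson correlations between neighbouring slices of
   the membrane channel; end slices whose correlation with their inward
   neighbour falls below 0.78 are trimmed, and stacks with fewer than three
   usable slices are rejected.
2. **Segmentation.** After 3D Gaussian smoothing (σ = 0.3 µm,
   anisotropy-aware), each slice of each channel is binarized at the median
   intensity of its edge pixels (Sobel edges); masks are refined by removing
   sub-5 µm³ clusters, filling enclosed cavities, and morphological closing,
   then split into nested nucleus ⊆ soma ⊆ cell compartments (branches =
   cell ∖ soma).
3. **Skeletonization and cell segregation.** An exact anisotropic Euclidean
   distance map of the cell mask is partitioned by marker-based watershed;
   segment centroids become the nodes of a skeleton graph with straight-line
   edges. Every node is assigned to the soma with the shortest
   edge-length-weighted path (`one cell per soma`), and cells are flagged when
   they touch a stack border with the soma closer than 15 µm (X/Y) / 8 µm
   (Z), or when connected somata lie closer than 15 µm.
4. **Features and statistics.** Per included cell: 12 simple-shape features
   (e.g. sphericity `π^(1/3)(6V)^(2/3)/A`, circularity `4πA/P²` of the
   z-projection), 29 skeleton features (node/branch counts, branch lengths,
   sinuosity), and 18 graph-theoretical features (closeness, betweenness,
   degree, global efficiency); node- and branch-level quantities are
   summarised by five percentiles (min, P25, median, P75, max). Downstream,
   each feature is screened by ROC AUC between two groups, features with
   folded AUC > 0.85 (best percentile variant only) enter a centred and
   scaled PCA, and PC1 serves as a compound morphology score. A Wilcoxon
   rank-sum test (with continuity correction) covers group comparisons, and
   every result row can be back-traced to its voxels in the source stack.

No study data ship with the package: a synthetic phantom generator renders
ramified and amoeboid cells with voxel-level ground truth, so the whole
pipeline is testable offline.

## Worked example

```r
library(microglia3d)

# render a small labelled phantom cohort (2 channels, ground truth included)
cohort <- phantom_cohort(n_ramified = 8, n_amoeboid = 8, seed = 1)
run <- run_pipeline(pipeline_config(cohort, seed = 1))
run
#> <mglia_run> 4/4 stacks processed, 17 cells (16 included)
#>   PC1 explains 83.5% of variance over 25 features

dplyr::filter(run$roc, feature %in%
  c("Sphericity", "Segments per branch", "Betweenness P75"))[,
  c("feature", "family", "auc", "direction")]
#> # A tibble: 3 × 4
#>   feature             family     auc direction
#>   <chr>               <chr>    <dbl> <chr>
#> 1 Sphericity          simple   1     amoeboid
#> 2 Segments per branch skeleton 1     ramified
#> 3 Betweenness P75     graph    0.625 amoeboid

glance(run$pca)
#> # A tibble: 1 × 4
#>   n_features n_cells pc1_variance_fraction pc2_variance_fraction
#>        <int>   <int>                 <dbl>                 <dbl>
#> 1         25      16                 0.835                0.0815
```

Reading: of the 17 detected cells, 16 passed the exclusion rules. Sphericity
separates the two phenotypes perfectly (amoeboid cells are more compact),
"Segments per branch" separates them in the opposite direction (ramified
cells carry more skeleton segments per major branch), and the PC1 compound
score condenses the 25 selected features into one axis that explains 83.5%
of their joint variance — higher PC1 = more ramified. `autoplot(run$pca)`
draws the PC1/PC2 score plot; `backtrace(run$stacks[[1]], cell_id = 2)`
returns the voxel coordinates and label crop of any result row.

File-based workflows use `read_stack()` / `write_stack()` (multi-page TIFF
with a JSON voxel-size sidecar; OME-TIFF metadata is parsed on read), or the
thin CLI in `inst/cli/microglia3d.R` with subcommands `run`, `synth`,
`stats`, and `backtrace`.

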