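---
title: "Automated 3D morphometry of microglia: models, parameters, and design choices"
author: "microglia3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated 3D morphometry of microglia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microglia3d` quantifies the morphology of microglial cells in two-channel
confocal Z-stacks. This vignette explains the model behind each stage, the
parameters that matter (with units and defaults), the choices we made where
the design was genuinely open, and what the synthetic phantoms do and do not
demonstrate about real data.

## Coordinate and intensity conventions

Voxel arrays are indexed `(z, y, x)`; the physical voxel size is
`c(dz, dy, dx)` in micrometres, default `c(0.4, 0.2, 0.2)` for acquired
stacks. Serialized voxel indices are 0-based and the physical coordinate of
a voxel centre is `index0 * voxel_size`, so border distances are measured to
the outermost voxel-centre planes. Intensities live on the raw integer scale
`[0, 2^bit_depth - 1]` and are never rescaled before thresholding.

## Slice quality control

Optical sections 0.4 µm apart image nearly the same tissue, so neighbouring
slices of a usable stack correlate strongly; a drop in signal-to-noise shows
up as a drop in inter-slice Pearson correlation. We compute the correlation
profile on the raw membrane-marker channel (the analysis target; the nuclear
stain is sparse and noisier, though the channel is configurable) and trim
slices from the two stack ends while the end slice's correlation with its
inward neighbour is below the threshold (default **0.78**, chosen upstream
to mimic a human rater). Interior slices are never touched, retained voxels
are bit-identical to the input, and trimming is idempotent. Stacks retaining
fewer than three slices are rejected. We deliberately apply no
deconvolution.

## Segmentation

Stacks are first smoothed with an anisotropy-aware Gaussian, per-axis sigma
`0.3 µm / voxel_size[axis]` in voxel units (reflective boundaries; the
default σ = 0.3 µm roughly matches the lateral PSF width).

Thresholds are chosen **per slice and per channel** from the intensities at
image edges: edge pixels sit on the foreground/background transition, so
their median intensity is a robust cut between the two populations. Edge
pixels are Sobel-gradient maxima; the gradient cut that defines them is
pooled over the whole stack (one Otsu threshold of the channel's gradient
magnitudes, floored at mean + 4 sd) because labelled structure is sparse
along z — a slice with no structure has only weak texture gradients, all
below the pooled cut, and correctly yields an empty mask rather than a
threshold fitted to background texture. Two guards handle degenerate slices:
a slice with no edge pixels gets the empty-mask sentinel (`max + 1`), and no
slice threshold may fall below the stack's background ceiling
(median + 3 MAD of the channel, estimated on a deterministic stride
subsample). The single-slice `edge_based_threshold()` falls back to a
whole-slice Otsu when the slice has gradients but no edges survive its own
Otsu cut.

Masks are refined by (i) removing 26-connected components smaller than
**5 µm³** (nuclear channel: a quarter of that) — well below the volume of
even an amoeboid soma but above noise specks; (ii) filling background
cavities fully enclosed in 3D (6-connected background, the standard duality
that avoids connectivity paradoxes); (iii) a morphological closing with a
1-voxel-radius box.

**Compartments.** The soma is reconstructed by a geodesic opening at the
core thickness: voxels whose distance to the cell surface is at least
`soma_core_distance_um` (default **1.2 µm**, i.e. a local diameter of
2.4 µm — thicker than any process, thinner than any soma) form the core;
core components are kept only when they overlap a nucleus, then dilated back
by the same physical distance within the cell mask so the eroded soma rind
is restored while processes stay out, and finally grown until the
overlapping nucleus is covered. Branches are the exact complement
`cell ∖ soma`, so the nesting `nucleus ∩ cell ⊆ soma ⊆ cell` holds by
construction. Nucleus components with no cell overlap or no soma core are
discarded and recorded — these are typically nuclei of other cell
populations, the main source of false-positive "cells".

## Skeleton graph

The cell mask's **exact anisotropic Euclidean distance transform**
(separable lower-envelope algorithm, verified against a brute-force oracle)
is segmented by marker-based watershed: markers are the 26-neighbourhood
local maxima of the distance map (plateaus merged), greedily thinned to a
minimum physical separation of **0.6 µm** — chosen so a sphere yields
exactly one segment — and regions grow by 6-connected priority flooding in
order of decreasing distance, so labels partition the mask deterministically.

Each watershed segment becomes a node at its voxel centroid; every
face-adjacent segment pair contributes a straight edge whose length is the
Euclidean centroid distance. Node compartments follow the majority of the
segment's voxels (soma vs branch) with the nucleus overlap fraction kept
alongside. Nodes are numbered canonically by sorting centroids on
`(z, y, x)`, which makes every downstream tie-break reproducible.

**Refinement** merges nodes with segment volume < **0.2 µm³** into their
largest face-adjacent neighbour and removes sub-**0.5 µm** spurs (degree-1
branch nodes hanging off a branching node), repeating to a fixpoint. A
pruned node's voxels are merged into its neighbour rather than dropped, so
the sum of node volumes always equals the mask volume exactly — an invariant
the tests assert after every stage.

**Major branches** are the connected components of the branch-node subgraph,
each owned by its lowest-id soma-adjacent node (the entry node). This is the
deterministic closure of "what you reach from one soma exit": a pendant
chain is one branch, a bifurcating subtree is one branch, and a loop that
touches the soma twice is one branch owned by the lower entry node. Branch
cycles are the circuit rank `E − N + C` of the branch subgraph.

## Cells

One cell per soma: each soma's centre node is the node containing the soma's
distance-map maximum (its thickest point), and every skeleton node joins the
soma with the smallest edge-length-weighted shortest-path distance
(igraph); equidistant nodes go to the smaller canonical centre id.
Exclusion rules follow the published thresholds: border contact with the
soma centroid within **15 µm** of an X/Y border or **8 µm** of a Z border;
somata of connected cells closer than **15 µm**; and (toggleable, default
on) somata without a nucleus. Cells are flagged, never deleted, and
`backtrace()` maps any result row back to its source file, retained slice
range, soma centroid, bounding box, and a cropped label volume.

## The 59-feature roster

The roster is frozen in code (`feature_roster()`) and fingerprinted
(`roster_hash()`); outputs cite the hash. Families: **12 simple** features
(sphericity `π^(1/3)(6V)^(2/3)/A`; circularity `4πA/P²` of the
z-projection, computed identically to the manual index; cell, soma, and
nucleus volumes; surface area; bounding-box extent ratio; five percentiles
of node volume), **29 skeleton** features (the published count/ratio labels
verbatim — nodes total, branching nodes, end-nodes, nodes/end-nodes in and
per branch, branch segments and segments per branch, branch cycles — plus
major branch count, soma nodes, total edges and skeleton length, and five
percentiles each of per-branch skeleton length, air-line length, and
sinuosity), and **18 graph** features (five percentiles each of closeness
`(n−1)/Σd`, betweenness normalised by `(n−1)(n−2)/2`, and degree, plus
diameter, characteristic path length, and global efficiency). Beyond the 17
published labels the roster is this package's own reconstruction, which is
why it is versioned.

Percentiles use linear interpolation (R's default quantile type 7) — stated
explicitly because percentile conventions differ across ecosystems. Branch
length "skeleton" is the in-branch shortest-path length from the entry node
to the path-farthest node, and the air-line length is the straight-line
distance between the same two nodes, so sinuosity = skeleton / air-line ≥ 1
by the triangle inequality. Ratio features with a zero denominator (e.g. a
soma-only cell) take the sentinel 0 and set the row's
`quality_degenerate` flag.

**Surface area** is measured on a triangulated isosurface: the binary
territory is padded, smoothed with a 1-voxel Gaussian, and triangulated by
marching tetrahedra at level 0.5 with anisotropic vertex placement. The
smoothing matters: triangulating the raw binary ball overestimates a
sphere's area by ~29%, while the smoothed surface is accurate to ~0.3%
(digital ball, r = 20 voxels). The 2D projection perimeter uses the same
idea with a marching-squares contour.

## Downstream statistics

ROC AUCs come from the rank-sum construction (mid-ranks, so ties count 0.5),
which the tests verify against trapezoidal ROC integration to 1e−12. AUCs
are folded to `max(A, 1−A)` with the direction recorded, because the screen
asks "does this feature discriminate", not "which way". Features with folded
AUC > **0.85** are kept, reduced to the single best percentile variant per
family (ties to the lower percentile), and passed to a centred, scaled PCA
(`prcomp`). PC1 is the compound score; its sign is oriented so PC1
correlates positively with "Segments per branch", i.e. higher = more
ramified. No multiple-testing correction is applied in the screen — it is a
selection step, not inference; group tests use the two-sided Wilcoxon
rank-sum test with continuity correction. The PCA is fitted on the pooled
cell table and the grouping is recorded with the model.

## Synthetic phantoms: what they emulate, and what they do not

`render_stack()` draws each cell as a soma ball plus random-walk tubes
(spheres rasterized every half branch-radius, so the union is dense and the
volume auditable), a nucleus ball in the nuclear channel, a smooth
z-correlated background texture (drawn independently per channel, amplitude
2.5× the i.i.d. noise — this keeps neighbouring-slice correlations near
0.85, the regime the QC rule presumes of usable tissue), and additive
Gaussian noise (default sd 5% of the dynamic range) clipped to the bit
range. Presets: **ramified** = 3 µm soma, 4–6 primary branches of
20 ± 5 µm, radius 0.7 µm, tortuous; **amoeboid** = 6 µm soma, 0–2 branches
of 5 ± 2 µm, radius 1.0 µm. Intensities are 180 foreground over 20
background (8-bit).

Problem sizes are chosen for single-core desk-scale runs and stated here as
the package's own defaults: the benchmark cohort is 20 + 20 cells in ten
single-phenotype stacks of 20 × 66 × 66 µm at 0.5 µm isotropic phantom
resolution (branch tubes remain ~3 voxels across); recovery layouts place
1/3/5 cells on jittered grids with ≥ 16 µm separation and ≥ 2 µm clearance
beyond the exclusion margins, so that placement jitter and
centroid-measurement error cannot push a soma over a threshold it was meant
to clear.

Phantoms contain no point-spread-function anisotropy, no photobleaching, no
depth-dependent attenuation, no touching somata, and no non-microglial
nuclei except as segmentation by-products. Passing the phantom benchmark
therefore demonstrates that the pipeline's geometry, graph, and statistics
machinery is correct and deterministic — not that segmentation accuracy on
real immunofluorescence matches it. On real data the published protocol's
parameters (0.78, 0.3 µm, 15/8/15 µm, AUC 0.85) are the defaults, and each
is exposed in `pipeline_config()`.

## Numerical choices and degenerate inputs

- Distance transform exact by construction; verified against brute force.
- Watershed flooding and marker thinning break ties by scan order —
  deterministic, and translation-invariant for interior objects.
- Constant slices: correlation defined as 0 (warning); threshold sentinel
  `max + 1` (empty mask).
- Empty masks: all-zero distance map with a warning; empty cell tables with
  all columns typed.
- A cell with a single node: closeness/betweenness/diameter all 0 by
  convention; betweenness is 0 for any graph with fewer than 3 nodes.
- The pipeline draws no random numbers; reruns of the same config are
  bit-identical. Randomness exists only in the phantom generator, which
  restores the caller's RNG state.

## Known limitations

- The per-slice edge-median threshold assumes sparse bright structure over
  darker background; densely labelled tissue would need a different rule.
- Somata are found via nucleus overlap: a microglia whose nucleus is outside
  the stack is dropped (by design, as a likely partial cell).
- Watershed over-segmentation is controlled but not eliminated; absolute
  node counts are resolution-dependent, which is why per-branch ratios and
  percentile summaries carry most of the discrimination.
- Surface area and circularity depend mildly on the smoothing radius; the
  defaults are validated on analytic shapes (sphere, cube, disk, square) to
  within a few per cent.
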