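# ailp — consensus voxelwise ROIs for studying brain network plasticity

Longitudinal resting-state fMRI studies face a dilemma: data-driven,
voxelwise parcellations are re-derived at every acquisition, so the regions
of interest (ROIs) found at Time 1 are not the regions found at Time 2, and
network metrics computed on them cannot be compared. `ailp` implements
**aggregate-initialized label propagation (AILP)**, a procedure that turns
two per-timepoint parcellations into a single consensus set of voxel-level
ROIs usable at both time points, while preserving the native signal in
every voxel.

The pipeline:

1. **Lattice graph.** Every in-mask gray-matter voxel is a node, joined to
   its 6 face-adjacent neighbors, with edges forbidden across the
   boundaries of coarse anatomical *meta-regions*. Each edge is weighted by
   the band-limited (0.005–0.12 Hz) magnitude-squared coherence of its
   endpoint BOLD series, estimated with Slepian multitapers and integrated
   over the band.
2. **Per-timepoint parcellation.** Louvain optimization of the weighted
   modularity
   *Q = (1/2m) Σᵢⱼ (Aᵢⱼ − kᵢkⱼ/2m) δ(Cᵢ, Cⱼ)*
   over the lattice yields the per-timepoint modules (iROIs).
3. **Aggregation.** Each voxel gets the ordered label pair
   (Time-1 label, Time-2 label); voxels sharing a pair form one module.
   This partition meet (aROIs) is exact but heavily fractionated.
4. **Label propagation.** Initialized from the aggregate, each voxel
   iteratively adopts the most frequent label among its 6 neighbors
   (asynchronous updates, random visit order, uniform random tie-breaks)
   until every voxel holds a maximal-frequency neighbor label. The result
   (lpROIs) reconstitutes the fragments into spatially coherent consensus
   ROIs.
5. **Network analysis.** Mean lpROI series are correlated pairwise
   (Pearson), thresholded by Benjamini–Hochberg FDR at α = 0.05, and
   summarized by link count, total strength, mean binary clustering
   coefficient, and mean binary shortest-path length.
6. **Reliability.** Stochasticity across repeated runs is quantified by the
   size-weighted Sørensen overlap of matched ROIs and by voxel-pair
   co-assignment consistency.

No clinical data ship with the package; a synthetic phantom generator
(`generate_phantom()`) produces masked 4D volumes with known, contiguous
signal blocks at two time points (partially perturbed block boundaries)
so that every stage is testable end to end.

## Worked example

```r
library(ailp)

spec    <- phantom_spec(seed = 11)      # 12x12x4 grid, 2 meta-regions x 2 blocks
phantom <- generate_phantom(spec)
grid    <- volume_grid(phantom$mask, phantom$atlas)
lattice <- build_lattice(grid)
#> lattice_graph: n = 576 voxels, m = 1440 edges (unweighted)

w1 <- weight_lattice(lattice, phantom$bold_t1)
w2 <- weight_lattice(lattice, phantom$bold_t2)
iroi_t1 <- louvain_partition(w1, seed = 1)
iroi_t2 <- louvain_partition(w2, seed = 2)
modularity_score(w1, iroi_t1)
#> [1] 0.766

aroi <- aggregate_parcellations(iroi_t1, iroi_t2)
fragmentation_report(aroi)
#> 23 ROIs; voxels/ROI mean 25.0 (sd 23.3) median 20.0; <5 voxels: 21.7%; <10 voxels: 39.1%

lproi <- ailp(lattice, iroi_t1, iroi_t2, seed = 1)
fragmentation_report(lproi)
#> 14 ROIs; voxels/ROI mean 41.1 (sd 24.8) median 40.0; <5 voxels: 7.1%; <10 voxels: 14.3%

runs <- lapply(1:10, function(s) ailp(lattice, iroi_t1, iroi_t2, seed = s))
run_consistency(runs, grid)
#> reliability over 10 runs (45 pairs): weighted Sørensen 0.960, voxel-pair consistency 0.986
```

The aggregation step fractionates the 8–9 per-timepoint modules into 23
aROIs, over a fifth of them smaller than 5 voxels; label propagation
reconstitutes them into 14 consensus lpROIs with almost no small
fragments, and repeated seeded runs agree to ~96–99%. `run_pipeline()`
performs the same sequence from NIfTI files on disk and writes every
intermediate (label maps, edge lists, adjacency matrices, fragmentation
and reliability reports, a hashed manifest).

A thin command-line wrapper with `simulate`, `parcellate`, `aggregate`,
`propagate`, `network`, `reliability`, and `run` subcommands is installed
at `system.file("cli", "ailp.R", package = "ailp")`.

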