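---
title: "Methods: aggregate-initialized label propagation for consensus voxelwise ROIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aggregate-initialized label propagation for consensus voxelwise ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Voxelwise, data-driven parcellation of BOLD fMRI produces a different set
of regions every time it is run — in particular at two acquisition time
points of a longitudinal study. Comparing network metrics across time
points requires a *single* consensus set of ROIs that respects both
parcellations while keeping the voxel-level signal intact. `ailp`
implements that consensus step — aggregation of the two parcellations
followed by label propagation initialized from the aggregate — together
with the surrounding stages: coherence-weighted lattice construction,
modularity parcellation, ROI-network metrics, and reliability scoring.

# Model and procedure

## Anatomically constrained voxel lattice

The voxel graph is a 6-connectivity lattice (face adjacency only,
diagonals excluded) over the in-mask voxels, with two constraints:

* **Mask.** A probability volume is binarized with a *strict* threshold
  (`binarize_mask()`, default 0.5): a voxel equal to the threshold is
  excluded. The convention matters only for ties at exactly 0.5 and is
  documented rather than configurable by inclusivity.
* **Meta-regions.** No edge joins voxels in different meta-regions, so
  labels can never propagate — and modules can never extend — across these
  coarse anatomical boundaries. The meta-region atlas is user-supplied
  configuration (any integer volume); the package deliberately hard-codes
  no specific anatomical lookup table, since published meta-region/atlas
  number mappings are not always internally consistent and users may wish
  to define their own territories.

In-mask voxels with no same-region neighbor are retained as degree-0
nodes; they become singleton ROIs downstream rather than being dropped.

## Coherence edge weights

Each lattice edge is weighted by the band-limited magnitude-squared
coherence (MSC) of its endpoint series:

* MSC is estimated by the multitaper method. Slepian tapers are computed
  from the standard symmetric-tridiagonal eigenproblem; defaults are a
  time-half-bandwidth product NW = 4 with K = 7 tapers (the usual
  2NW − 1 choice, a bias/variance compromise for series of ~100–150
  samples). With K tapers the MSC of independent signals is biased upward
  by roughly 1/K ≈ 0.14; this floor is shared by all edges and therefore
  harmless for partitioning.
* The MSC spectrum is integrated over 0.005–0.12 Hz (trapezoidal rule,
  linear interpolation at the band edges), the conventional band of
  resting-state BOLD fluctuations; both limits are arguments. The
  integral is divided by the band width so weights lie in [0, 1]. The
  raw area (`normalize = FALSE`) differs only by the constant factor
  `f_hi − f_lo`, which rescales all weights equally and leaves the
  modularity-optimal partition unchanged.
* No detrending or filtering is applied beyond the band restriction:
  preprocessing is upstream of this package.

## Per-timepoint parcellation

Modules are found by Louvain optimization of the weighted modularity
*Q* (resolution 1.0 by default, exposed as an argument).
`modularity_score()` evaluates *Q* exactly per its definition;
`louvain_partition()` delegates the greedy two-phase optimization to
igraph, with the node visit order randomized from the supplied seed so a
fixed seed gives bit-reproducible partitions. Louvain is single-run by
contract: no restarts, ties resolved however the greedy pass encounters
them. The consensus machinery accepts any externally produced label map
in place of Louvain output (`volume_to_parcellation()`).

Self-loops do not exist in the lattice and are disallowed by the graph
container.

## Aggregation (partition meet)

Voxels are co-assigned in the aggregate iff co-assigned in both inputs —
equivalently, each voxel is labeled with its ordered pair of per-timepoint
labels and equal pairs are joined. Aggregation is deterministic and
parameter-free. Exactly two time points are supported; the meet
generalizes to more, but that territory is untested here and deliberately
not exposed.

## Label propagation

`label_propagation()` implements the asynchronous update: within a sweep,
voxels are visited in a fresh random order; already-updated voxels
contribute their new labels and not-yet-visited voxels their previous
ones. For each voxel the most frequent label among its neighbors is
adopted; ties are broken uniformly at random. Details fixed by design:

* **The focal voxel's own label does not vote** — the vote ranges over
  neighbors only.
* **Voting is unweighted.** Coherence weights drive the modularity step
  only; label propagation counts neighbor label frequencies.
* **Stopping rule.** The algorithm concludes when every voxel's label is
  among the maximal-frequency labels of its neighborhood. A voxel whose
  label is merely *tied* for maximal frequency is satisfied and does not
  force another sweep; without this reading, tied configurations would
  re-randomize forever.
* **Asynchronous, not synchronous.** Synchronous (Jacobi-style) updates
  are known to oscillate on bipartite-like structures; the asynchronous
  scheme avoids this.
* **Guard.** `max_sweeps` (default 100) bounds the sweep count with a loud
  warning if reached; convergence on realistic inputs takes a handful of
  sweeps (per-sweep change counts are returned as an attribute and
  logged by the pipeline).
* **No size filtering.** Small lpROIs are reported, never deleted; users
  wanting a minimum ROI size should filter downstream.

Output labels are densified to consecutive integers in first-occurrence
order for stable file output.

## ROI networks and global metrics

Mean lpROI series are correlated pairwise (Pearson); p-values use the t
approximation with T − 2 degrees of freedom, corrected by
Benjamini–Hochberg FDR over the n(n − 1)/2 tests at α (default 0.05),
applied per matrix. Surviving edges carry their *signed* r as weight; a
`positive_only` flag discards negative edges for users who prefer that.
Conventions for the global metrics:

* link count and strength sum surviving unordered pairs (strength is the
  signed sum);
* mean clustering uses the binary adjacency; nodes of degree < 2, where
  the defining ratio is 0/0, contribute 0;
* path length uses binary connections only (weighted path length is hard
  to interpret in functional networks); on disconnected graphs the mean
  is over reachable ordered pairs, with a `disconnected` attribute set,
  and an edgeless graph is an error (the pipeline reports `NA` there).
* constant ROI series have undefined correlations; their pairs are
  excluded from testing with a warning;
* p-values carry no autocorrelation correction — a known limitation for
  serially correlated BOLD series.

## Reliability

Two scores quantify run-to-run stochasticity of label propagation
(visit order and tie-breaks), computed over all unordered pairs of runs:

* **Size-weighted Sørensen overlap.** Within each meta-region, each ROI
  of either run is matched to the ROI of the other run with maximal voxel
  overlap (best-match per ROI, pooled over both directions — *not*
  one-to-one), its Sørensen index `2|X∩Y|/(|X|+|Y|)` computed, and the
  scores averaged weighted by ROI size. Best-match pooling was chosen
  because it is symmetric and reproduces the intended hand-checkable
  behavior for a split ROI (a 10-voxel ROI split into 5 + 5 against the
  intact ROI scores 2/3); a strict one-to-one matching with zero-scored
  unmatched ROIs would punish exactly reproducible splits twice.
* **Voxel-pair consistency.** For voxel pairs within a meta-region, the
  fraction of runs agreeing with the modal outcome (co-assigned vs not),
  averaged over pairs; pairs are enumerated exactly up to `max_pairs`
  (default 10⁶) and estimated by seeded Monte-Carlo pair sampling beyond
  that.

# The phantom generator

`generate_phantom()` is the package's test bed and defines its study
conditions. Geometry: meta-regions are axis-aligned slabs of the grid
(along x), each tiled by contiguous blocks (slabs along y) — trivial to
reason about and sufficient to exercise every constraint. Signals: each
block carries one source, a sum of K = 3 unit-amplitude sinusoids with
random phases, plus iid Gaussian voxel noise (`noise_sd`, default 0.5,
i.e. noise sd ≈ 0.4× the source sd — clearly sub-dominant but far from
clean). Source frequencies are drawn uniformly from the
Fourier-resolvable frequencies inside the signal band, sampled without
replacement *across* blocks, so that (a) out-of-band leakage is
essentially zero, making the spectral-confinement invariant exactly
testable, and (b) distinct blocks have orthogonal sources, making
within-block versus cross-block coherence separable by construction. The
second time point re-assigns a fraction (default 0.15) of block-boundary
voxels to an adjacent block, one voxel at a time, rejecting moves that
would break the donor block's 6-connectivity; sources and noise are drawn
fresh. Defaults are 145 volumes at a 2 s sampling interval with the
0.005–0.12 Hz band, matching a typical resting-state acquisition.

What the phantom does *not* emulate: hemodynamic response convolution,
physiological and motion artifacts, spatial smoothness of noise, partial
volume effects, and any realistic anatomy. Passing tests therefore
demonstrate algorithmic correctness and stability under idealized
block-structured signals, not performance on clinical data.

## Modularity's resolution limit and fixture sizes

Modularity compares intra-community weight against a null term that
depends on the *global* edge weight. Two consequences shape the test
fixtures:

* Large homogeneous blocks are subdivided: on a uniform-weight lattice,
  splitting a big block raises Q (the cut cost is outweighed by the null
  term's reduction). Empirically, one-region two-block phantoms are
  recovered exactly at 2×4×2 (8-voxel blocks) but split at 4×4×2 and
  above. The planted-block *recovery* fixture is therefore the 2×4×2
  phantom, where exact recovery (adjusted Rand index 1) is the correct
  optimum; the larger 12×12×4 default phantom is used where block-exact
  recovery is not required (fragmentation-and-repair behavior,
  reliability), since there Louvain legitimately parcellates blocks into
  patches, just as whole-brain modularity yields hundreds of modules.
* Per-meta-region decomposability is only approximate: although no edges
  cross regions, the null term couples regions through the total weight,
  so running Louvain per region can split where the whole-graph run does
  not. The corresponding test asserts agreement on a fixture (4×4×2, two
  regions) sized so the optimum coincides.

# Numerical choices

* Louvain convergence and tie handling are igraph's; determinism comes
  from seeding R's RNG around the call. The pipeline derives the Time-2
  Louvain seed as `louvain$seed + 1` so one config entry yields two
  independent draws; the label-propagation seed is a separate entry.
* Slepian tapers are cached per (length, NW, K); sign convention follows
  the usual polarity rule (positive mean for symmetric tapers), though
  taper sign cancels in MSC.
* MSC values are clipped to [0, 1] against floating-point overshoot.
* Band integration requires at least 2 frequency samples inside the band
  and errors otherwise (series too short for the requested band).
* Correlations of ±1 produce t statistics at the floating-point limit
  (p ≈ 0), handled by clamping the denominator.
* The fragmentation report uses the sample standard deviation (n − 1);
  a single-module parcellation reports `NA` there.

# Validation problem sizes

The test suite and the acceptance script regenerate everything from code:
brute-force oracle comparisons use 100 random graphs of up to 30 nodes
(modularity, double loop), 100 graphs of up to 25 nodes (clustering via
triangle enumeration, path length via Floyd–Warshall), 50 random
masks/atlases of up to 4³ voxels (lattice construction), and 200 random
partition pairs of up to 100 voxels (the meet property). Pipeline-level
checks use the 2×4×2 recovery phantom and the 12×12×4 standard phantom
(576 voxels, 145 volumes), with 10 seeded label-propagation runs for the
reliability scores and 50 replicates of a 20-ROI null for the FDR check.
These sizes make the full validation run in well under a minute while
keeping every oracle exact.

# Known limitations

* Pearson p-values ignore temporal autocorrelation; with strongly
  autocorrelated series the FDR threshold is anti-conservative.
* Modularity's resolution limit means the iROI scale is set by the data
  size, not by anatomy; AILP consolidates but cannot merge beyond the
  aggregate's structure.
* The reliability module measures algorithmic stochasticity only, not
  test–retest reliability across sessions (between-session change is the
  plasticity signal, not noise).
* Exactly two time points are supported end to end.
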