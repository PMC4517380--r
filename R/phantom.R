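#' Specification for a synthetic 4D phantom
#'
#' Defines a masked 4D BOLD-like dataset with known community structure:
#' the grid is split into axis-aligned meta-region slabs (along x), each
#' tiled by contiguous signal blocks (slabs along y). Every block's voxels
#' share one band-limited source signal plus independent Gaussian noise.
#' Two "time points" are generated; the second reassigns a fraction of
#' block-boundary voxels to an adjacent block, emulating plasticity of the
#' functional parcellation between acquisitions.
#'
#' Defaults mirror a resting-state acquisition: 145 retained volumes at a
#' repetition time of 2 s, with signal confined to the 0.005-0.12 Hz band.
#'
#' @param grid_dims integer triple of voxels per axis (each >= 2).
#' @param n_meta_regions number of meta-region slabs along x.
#' @param blocks_per_region contiguous signal blocks per meta-region.
#' @param n_volumes time points per series (>= 16).
#' @param sampling_interval_s repetition time in seconds.
#' @param signal_band_hz two-element band; upper bound must be below the
#'   Nyquist frequency.
#' @param noise_sd standard deviation of iid voxelwise Gaussian noise
#'   (the sources have unit-amplitude sinusoid components).
#' @param perturbation_fraction fraction of block-boundary voxels moved to
#'   an adjacent block at the second time point, in \[0, 1\].
#' @param seed integer seed; the dataset is a deterministic function of the
#'   spec including the seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dims = c(12L, 12L, 4L),
                         n_meta_regions = 2L,
                         blocks_per_region = 2L,
                         n_volumes = 145L,
                         sampling_interval_s = 2.0,
                         signal_band_hz = c(0.005, 0.12),
                         noise_sd = 0.5,
                         perturbation_fraction = 0.15,
                         seed = 1L) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 2L))
    stop("'grid_dims' must be three integers, each >= 2")
  if (n_meta_regions < 1L || blocks_per_region < 1L)
    stop("'n_meta_regions' and 'blocks_per_region' must be positive")
  if (grid_dims[1L] < n_meta_regions)
    stop("grid too small along x for ", n_meta_regions, " meta-region slabs")
  if (grid_dims[2L] < blocks_per_region)
    stop("grid too small along y to tile ", blocks_per_region,
         " contiguous blocks per meta-region")
  if (n_volumes < 16L) stop("'n_volumes' must be >= 16 for spectral estimation")
  if (sampling_interval_s <= 0) stop("'sampling_interval_s' must be positive")
  nyq <- 1 / (2 * sampling_interval_s)
  if (length(signal_band_hz) != 2L || signal_band_hz[1L] <= 0 ||
      signal_band_hz[1L] >= signal_band_hz[2L] || signal_band_hz[2L] >= nyq)
    stop("'signal_band_hz' must satisfy 0 < lo < hi < Nyquist = ", nyq, " Hz")
  if (noise_sd < 0) stop("'noise_sd' must be nonnegative")
  if (perturbation_fraction < 0 || perturbation_fraction > 1)
    stop("'perturbation_fraction' must lie in [0, 1]")
  structure(list(grid_dims = grid_dims,
                 n_meta_regions = as.integer(n_meta_regions),
                 blocks_per_region = as.integer(blocks_per_region),
                 n_volumes = as.integer(n_volumes),
                 sampling_interval_s = sampling_interval_s,
                 signal_band_hz = signal_band_hz,
                 noise_sd = noise_sd,
                 perturbation_fraction = perturbation_fraction,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

## split 1..n into k contiguous runs, as balanced as possible
slab_assign <- function(n, k) {
  sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
  rep(seq_len(k), times = sizes)
}

## band-limited block source: sum of K sinusoids at distinct Fourier bins
## (bins allocated without replacement across blocks so that distinct blocks
## have mutually orthogonal sources)
make_sources <- function(n_blocks, spec, k_sin = 3L) {
  n <- spec$n_volumes; dt <- spec$sampling_interval_s
  f_all <- (seq_len(n %/% 2L)) / (n * dt)
  bins <- which(f_all >= spec$signal_band_hz[1L] &
                f_all <= spec$signal_band_hz[2L])
  if (length(bins) < k_sin * n_blocks)
    stop("signal band holds only ", length(bins), " resolvable frequencies; ",
         k_sin * n_blocks, " needed for ", n_blocks, " orthogonal blocks")
  picks <- matrix(sample(bins, k_sin * n_blocks), nrow = k_sin)
  tt <- (seq_len(n) - 1) * dt
  S <- matrix(0, nrow = n_blocks, ncol = n)
  for (b in seq_len(n_blocks)) {
    for (j in seq_len(k_sin)) {
      f <- f_all[picks[j, b]]
      S[b, ] <- S[b, ] + sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi))
    }
  }
  S
}

## voxels of `labels` lying on a block boundary (a same-meta 6-neighbor has
## a different label); returns linear indices
boundary_voxels <- function(labels_vol, meta, dims) {
  idx <- which(labels_vol > 0L)
  nb <- face_neighbors(idx, dims)
  diff_lab <- labels_vol[nb[, "from"]] != labels_vol[nb[, "to"]] &
    meta[nb[, "from"]] == meta[nb[, "to"]] & labels_vol[nb[, "to"]] > 0L
  sort(unique(nb[, "from"][diff_lab]))
}

#' Generate a synthetic phantom dataset
#'
#' Builds the full test-bed: ground-truth block parcellations for two time
#' points, a 4D BOLD-like series per time point (shared block source plus
#' iid noise), the all-true mask, and the meta-region atlas. The second
#' time point's blocks are derived from the first by moving a fraction of
#' boundary voxels into an adjacent block, one voxel at a time, rejecting
#' any move that would break the 6-connectivity of the donor block (so both
#' truths are contiguous within one meta-region).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_dataset`: list with `bold_t1`,
#'   `bold_t2` (4D arrays), `mask`, `atlas`, `truth_t1`, `truth_t2`
#'   ([parcellation()]s with provenance `"truth"`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid_dims
  mask <- array(TRUE, dims)
  x_reg <- slab_assign(dims[1L], spec$n_meta_regions)
  meta <- array(x_reg[slice.index(array(0L, dims), 1L)], dims)
  y_blk <- slab_assign(dims[2L], spec$blocks_per_region)
  blk_in_reg <- array(y_blk[slice.index(array(0L, dims), 2L)], dims)
  truth1 <- (meta - 1L) * spec$blocks_per_region + blk_in_reg
  n_blocks <- spec$n_meta_regions * spec$blocks_per_region

  with_local_seed(spec$seed, {
    ## perturb boundary voxels for time point 2
    truth2 <- truth1
    bnd <- boundary_voxels(truth1, meta, dims)
    n_move <- round(spec$perturbation_fraction * length(bnd))
    if (n_move > 0L) {
      cand <- bnd[sample.int(length(bnd))]
      moved <- 0L
      for (v in cand) {
        if (moved >= n_move) break
        nb <- face_neighbors(v, dims)[, "to"]
        nb <- nb[meta[nb] == meta[v] & truth2[nb] != truth2[v]]
        if (!length(nb)) next
        target <- truth2[if (length(nb) == 1L) nb else sample(nb, 1L)]
        donor <- which(truth2 == truth2[v])
        rest <- setdiff(donor, v)
        if (!length(rest) || !is_connected_6(rest, dims)) next
        truth2[v] <- target
        moved <- moved + 1L
      }
    }

    ## per-timepoint band-limited sources and noisy voxel series
    nt <- spec$n_volumes
    nvox <- prod(dims)
    bold <- function(truth) {
      S <- make_sources(n_blocks, spec)
      B <- S[as.vector(truth), , drop = FALSE] +
        spec$noise_sd * matrix(stats::rnorm(nvox * nt), nvox, nt)
      array(B, c(dims, nt))
    }
    bold_t1 <- bold(truth1)
    bold_t2 <- bold(truth2)
  })

  vox <- which(mask)
  structure(list(
    bold_t1 = bold_t1, bold_t2 = bold_t2,
    mask = mask, atlas = meta,
    truth_t1 = parcellation(truth1[vox], vox, provenance = "truth"),
    truth_t2 = parcellation(truth2[vox], vox, provenance = "truth"),
    spec = spec
  ), class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf(
    "phantom_dataset: %s grid, %d meta-regions x %d blocks, %d volumes, noise sd %.2f\n",
    paste(x$spec$grid_dims, collapse = "x"), x$spec$n_meta_regions,
    x$spec$blocks_per_region, x$spec$n_volumes, x$spec$noise_sd))
  invisible(x)
}

#' Toy lattice from an explicit label array
#'
#' Builds a fully masked single-meta-region lattice over a small 2D or 3D
#' integer label array, together with the labeling as a parcellation —
#' convenient for hand-checkable label-propagation fixtures.
#'
#' @param labels integer 2D or 3D array (a 2D array gets a singleton third
#'   axis).
#' @return list with elements `lattice` (a `lattice_graph`), `part` (a
#'   [parcellation()] with provenance `"truth"`), and `grid`.
#' @export
generate_toy_lattice <- function(labels) {
  d <- dim(labels)
  if (is.null(d) || !(length(d) %in% 2:3))
    stop("'labels' must be a 2D or 3D array")
  if (length(d) == 2L) dim(labels) <- c(d, 1L)
  dims <- dim(labels)
  grid <- volume_grid(array(TRUE, dims), array(1L, dims))
  lat <- build_lattice(grid)
  list(lattice = lat,
       part = parcellation(as.integer(labels)[lat$voxels], lat$voxels,
                           provenance = "truth"),
       grid = grid)
}
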