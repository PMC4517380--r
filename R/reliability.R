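#' Sørensen overlap of two voxel sets
#'
#' \eqn{s_{XY} = 2 |X \cap Y| / (|X| + |Y|)}: 1 iff the sets are equal,
#' 0 iff disjoint, symmetric.
#'
#' @param x,y nonempty vectors interpreted as sets (duplicates ignored).
#' @return scalar in \[0, 1\].
#' @export
sorensen <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (!length(x) || !length(y)) stop("Sørensen index undefined for empty sets")
  2 * length(intersect(x, y)) / (length(x) + length(y))
}

## per run pair & meta-region: each ROI of either run is matched to the
## maximal-overlap ROI of the other run; Sørensen per matched pair,
## averaged weighted by ROI size
pair_weighted_sorensen <- function(la, lb) {
  ct <- table(la, lb)                  # contingency of voxel counts
  ra <- rowSums(ct); cb <- colSums(ct)
  num <- 0; den <- 0
  for (i in seq_along(ra)) {
    j <- which.max(ct[i, ])
    num <- num + ra[i] * (2 * ct[i, j] / (ra[i] + cb[j]))
    den <- den + ra[i]
  }
  for (j in seq_along(cb)) {
    i <- which.max(ct[, j])
    num <- num + cb[j] * (2 * ct[i, j] / (ra[i] + cb[j]))
    den <- den + cb[j]
  }
  c(num = as.numeric(num), den = as.numeric(den))
}

#' Run-to-run reliability of AILP parcellations
#'
#' Quantifies the algorithmic stochasticity of repeated label-propagation
#' runs on the same data via two scores:
#'
#' * **Size-weighted Sørensen overlap.** For every unordered pair of runs
#'   and every meta-region, each lpROI is matched to the lpROI of the other
#'   run with which it shares the most voxels; the Sørensen index of each
#'   matched pair is averaged, weighted by lpROI size, then averaged over
#'   run pairs.
#' * **Voxel-pair consistency.** For voxel pairs within a meta-region, the
#'   fraction of runs agreeing with the modal co-assignment outcome
#'   (same-ROI vs different-ROI), averaged over pairs. Pairs are
#'   enumerated exactly when their number does not exceed `max_pairs`,
#'   otherwise estimated by seeded Monte-Carlo sampling of pairs.
#'
#' @param runs list of two or more [parcellation()]s on the same voxel set.
#' @param grid the [volume_grid()] supplying meta-region membership.
#' @param max_pairs cap on exact voxel-pair enumeration (default 1e6).
#' @param seed seed for pair subsampling.
#' @return An object of class `reliability_report`: list with
#'   `weighted_sorensen`, `voxel_pair_consistency`, `n_runs`,
#'   `n_run_pairs`, and a per-meta-region breakdown `per_region`.
#' @export
run_consistency <- function(runs, grid, max_pairs = 1e6, seed = 1L) {
  stopifnot(inherits(grid, "volume_grid"))
  if (length(runs) < 2L) stop("need at least 2 runs")
  vox <- runs[[1L]]$voxels
  for (r in runs)
    if (!identical(r$voxels, vox)) stop("runs cover different voxel sets")
  k <- length(runs)
  meta <- grid$meta[vox]
  regions <- sort(unique(meta))
  L <- vapply(runs, function(p) p$labels, integer(length(vox)))

  pairs <- utils::combn(k, 2L)
  reg_num <- setNames(numeric(length(regions)), regions)
  reg_den <- reg_num
  sor_by_pair <- numeric(ncol(pairs))
  for (pp in seq_len(ncol(pairs))) {
    a <- pairs[1L, pp]; b <- pairs[2L, pp]
    num <- 0; den <- 0
    for (ri in seq_along(regions)) {
      sel <- meta == regions[ri]
      ws <- pair_weighted_sorensen(L[sel, a], L[sel, b])
      num <- num + ws["num"]; den <- den + ws["den"]
      reg_num[ri] <- reg_num[ri] + ws["num"]
      reg_den[ri] <- reg_den[ri] + ws["den"]
    }
    sor_by_pair[pp] <- num / den
  }

  vp_region <- setNames(numeric(length(regions)), regions)
  vp_weight <- vp_region
  with_local_seed(seed, {
    for (ri in seq_along(regions)) {
      pos <- which(meta == regions[ri])
      np <- length(pos)
      if (np < 2L) { vp_region[ri] <- NA_real_; next }
      n_all <- np * (np - 1) / 2
      if (n_all <= max_pairs) {
        idx <- utils::combn(np, 2L)
        u <- pos[idx[1L, ]]; v <- pos[idx[2L, ]]
        vp_weight[ri] <- n_all
      } else {
        u <- pos[sample.int(np, max_pairs, replace = TRUE)]
        v <- pos[sample.int(np, max_pairs, replace = TRUE)]
        ok <- u != v
        u <- u[ok]; v <- v[ok]
        vp_weight[ri] <- n_all
      }
      same <- L[u, , drop = FALSE] == L[v, , drop = FALSE]
      cnt <- rowSums(same)
      vp_region[ri] <- mean(pmax(cnt, k - cnt) / k)
    }
  })
  has_vp <- !is.na(vp_region)
  structure(list(
    weighted_sorensen = mean(sor_by_pair),
    voxel_pair_consistency =
      sum(vp_region[has_vp] * vp_weight[has_vp]) / sum(vp_weight[has_vp]),
    n_runs = k,
    n_run_pairs = ncol(pairs),
    per_region = data.frame(
      meta_id = regions,
      weighted_sorensen = as.numeric(reg_num / reg_den),
      voxel_pair_consistency = as.numeric(vp_region)
    )
  ), class = "reliability_report")
}

#' @export
print.reliability_report <- function(x, ...) {
  cat(sprintf(
    "reliability over %d runs (%d pairs): weighted Sørensen %.3f, voxel-pair consistency %.3f\n",
    x$n_runs, x$n_run_pairs, x$weighted_sorensen, x$voxel_pair_consistency))
  invisible(x)
}
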