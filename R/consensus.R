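#' Aggregate two parcellations (partition meet)
#'
#' Combines per-timepoint parcellations by assigning each voxel the ordered
#' pair (Time-1 label, Time-2 label) and joining voxels sharing the same
#' pair into one module. The result is the partition meet: two voxels are
#' co-assigned iff they are co-assigned in *both* inputs. Output labels are
#' dense integers in first-occurrence order (over the voxel ordering).
#'
#' Aggregation typically fractionates the inputs — where two similar but
#' non-identical modules overlap, slivers of one or two voxels appear as
#' independent modules; label propagation repairs this downstream.
#'
#' @param p1,p2 [parcellation()] objects total over the same voxel set.
#' @return A [parcellation()] with provenance `"aROI"`.
#' @export
aggregate_parcellations <- function(p1, p2) {
  stopifnot(inherits(p1, "parcellation"), inherits(p2, "parcellation"))
  if (!identical(p1$voxels, p2$voxels))
    stop("parcellations cover different voxel sets")
  key <- paste(p1$labels, p2$labels)
  parcellation(match(key, unique(key)), p1$voxels, provenance = "aROI")
}

## maximal-frequency labels among a neighborhood
argmax_labels <- function(nlab) {
  u <- unique(nlab)
  cnt <- tabulate(match(nlab, u))
  u[cnt == max(cnt)]
}

#' Label propagation on the voxel lattice
#'
#' Iteratively reassigns each voxel to the label occurring with the highest
#' frequency among its lattice neighbors, with ties broken uniformly at
#' random. Updates are asynchronous: voxels are visited in a fresh random
#' order each sweep, and already-updated voxels contribute their new labels
#' while not-yet-visited voxels contribute their previous ones. The
#' algorithm concludes when every voxel's label is among the
#' maximal-frequency labels of its neighborhood.
#'
#' The focal voxel's own label does not vote, and neighbor voting is
#' unweighted (label frequency, not coherence weight). Degree-0 voxels keep
#' their initial label. Because the lattice has no cross-meta-region edges,
#' labels never propagate across meta-regions.
#'
#' @param lattice a `lattice_graph`; only its (unweighted) adjacency is
#'   used.
#' @param init initial [parcellation()], total over the lattice voxels.
#' @param seed integer seed driving visit order and tie-breaks.
#' @param max_sweeps guard against oscillation; a warning is emitted if it
#'   is reached before stabilization. Default 100 (convergence is typically
#'   near-linear, a handful of sweeps).
#' @return A [parcellation()] with provenance `"lpROI"` and dense labels in
#'   first-occurrence order. The integer vector of per-sweep label-change
#'   counts is attached as attribute `"sweep_changes"`.
#' @export
label_propagation <- function(lattice, init, seed = 1L, max_sweeps = 100L) {
  stopifnot(inherits(lattice, "lattice_graph"), inherits(init, "parcellation"))
  if (!identical(init$voxels, lattice$voxels))
    stop("'init' is not aligned with the lattice voxel set")
  nl <- neighbor_list(lattice)
  lab <- init$labels
  n <- length(lab)
  changes <- integer(0)
  stable <- FALSE
  with_local_seed(seed, {
    for (s in seq_len(max_sweeps)) {
      ord <- sample.int(n)
      ch <- 0L
      for (i in ord) {
        nb <- nl[[i]]
        if (!length(nb)) next
        best <- argmax_labels(lab[nb])
        newl <- if (length(best) == 1L) best
                else best[sample.int(length(best), 1L)]
        if (newl != lab[i]) ch <- ch + 1L
        lab[i] <- newl
      }
      changes[s] <- ch
      stable <- TRUE
      for (i in seq_len(n)) {
        nb <- nl[[i]]
        if (!length(nb)) next
        if (!(lab[i] %in% argmax_labels(lab[nb]))) { stable <- FALSE; break }
      }
      if (stable) break
    }
  })
  if (!stable)
    warning("label propagation hit max_sweeps = ", max_sweeps,
            " before stabilizing; returning the current labeling",
            call. = FALSE)
  out <- parcellation(match(lab, unique(lab)), lattice$voxels,
                      provenance = "lpROI")
  attr(out, "sweep_changes") <- changes
  out
}

#' Aggregate-initialized label propagation (AILP)
#'
#' The consensus step: the two per-timepoint parcellations are merged by the
#' partition meet ([aggregate_parcellations()]) and the aggregate is used to
#' initialize [label_propagation()], which reconstitutes the fractionated
#' aggregate modules into spatially coherent consensus ROIs (lpROIs) shared
#' by both time points.
#'
#' @param lattice the voxel `lattice_graph`.
#' @param p1,p2 per-timepoint [parcellation()]s.
#' @param seed seed for the label propagation step.
#' @param max_sweeps passed to [label_propagation()].
#' @return A [parcellation()] with provenance `"lpROI"`.
#' @export
ailp <- function(lattice, p1, p2, seed = 1L, max_sweeps = 100L) {
  label_propagation(lattice, aggregate_parcellations(p1, p2),
                    seed = seed, max_sweeps = max_sweeps)
}

#' Fragmentation statistics of a parcellation
#'
#' Summarizes per-module voxel counts: number of modules, mean / sample
#' standard deviation / median size, and the fractions of modules smaller
#' than 5 and than 10 voxels. Used to quantify how strongly aggregation
#' fractionates the per-timepoint modules and how much label propagation
#' repairs it.
#'
#' @param part a [parcellation()].
#' @return An object of class `fragmentation_report`: list with `n_rois`,
#'   `size_mean`, `size_sd`, `size_median`, `frac_lt5`, `frac_lt10`.
#' @export
fragmentation_report <- function(part) {
  stopifnot(inherits(part, "parcellation"))
  sizes <- as.integer(table(part$labels))
  structure(list(
    n_rois = length(sizes),
    size_mean = mean(sizes),
    size_sd = if (length(sizes) > 1L) stats::sd(sizes) else NA_real_,
    size_median = stats::median(sizes),
    frac_lt5 = mean(sizes < 5L),
    frac_lt10 = mean(sizes < 10L)
  ), class = "fragmentation_report")
}

#' @export
print.fragmentation_report <- function(x, ...) {
  cat(sprintf(
    "%d ROIs; voxels/ROI mean %.1f (sd %s) median %.1f; <5 voxels: %.1f%%; <10 voxels: %.1f%%\n",
    x$n_rois, x$size_mean,
    if (is.na(x$size_sd)) "NA" else sprintf("%.1f", x$size_sd),
    x$size_median, 100 * x$frac_lt5, 100 * x$frac_lt10))
  invisible(x)
}
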