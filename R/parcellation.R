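#' Parcellation container
#'
#' A total assignment of graph voxels to integer ROI labels. The `provenance`
#' tag records the pipeline stage that produced the labeling: per-timepoint
#' modularity modules (`iROI`), the aggregated partition meet (`aROI`), the
#' label-propagated consensus (`lpROI`), or phantom ground truth (`truth`).
#'
#' @param labels integer vector, one label per voxel; labels need not be
#'   consecutive.
#' @param voxels integer vector of voxel linear indices, aligned with
#'   `labels`.
#' @param provenance one of `"iROI"`, `"aROI"`, `"lpROI"`, `"truth"`.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, voxels,
                         provenance = c("iROI", "aROI", "lpROI", "truth")) {
  provenance <- match.arg(provenance)
  labels <- as.integer(labels)
  voxels <- as.integer(voxels)
  if (length(labels) != length(voxels))
    stop("'labels' and 'voxels' must have equal length")
  if (anyNA(labels)) stop("labels must be complete (partition is total)")
  structure(list(labels = labels, voxels = voxels, provenance = provenance),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("parcellation (%s): %d voxels in %d modules\n",
              x$provenance, length(x$voxels), length(unique(x$labels))))
  invisible(x)
}

total_edge_weight <- function(graph) {
  if (is.null(graph$weights)) nrow(graph$edges) else sum(graph$weights)
}

#' Weighted modularity of a partition
#'
#' Evaluates Newman's modularity
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left(A_{ij} - \frac{k_i k_j}{2m}\right)
#'   \delta(C_i, C_j)}
#' where \eqn{A_{ij}} is the (weighted) adjacency matrix, \eqn{k_i} the sum
#' of weights incident to node i, and \eqn{m} the total edge weight. Greater
#' Q indicates a stronger community structure. Computed per community as
#' \eqn{\sum_c [W_c/m - (S_c/2m)^2]} with \eqn{W_c} the intra-community edge
#' weight and \eqn{S_c} the community strength, which equals the double-loop
#' definition.
#'
#' @param graph a `lattice_graph` (an unweighted graph counts each edge with
#'   weight 1).
#' @param part a [parcellation()] total over the graph's voxels.
#' @return scalar Q in \[-1, 1\].
#' @export
modularity_score <- function(graph, part) {
  stopifnot(inherits(graph, "lattice_graph"), inherits(part, "parcellation"))
  if (!identical(part$voxels, graph$voxels))
    stop("partition is not aligned with the graph's voxel set")
  m <- total_edge_weight(graph)
  if (m <= 0) stop("graph has zero total edge weight: modularity undefined")
  w <- if (is.null(graph$weights)) rep(1, nrow(graph$edges)) else graph$weights
  lab <- part$labels
  n <- length(graph$voxels)
  strength <- numeric(n)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    strength[e[r, 1L]] <- strength[e[r, 1L]] + w[r]
    strength[e[r, 2L]] <- strength[e[r, 2L]] + w[r]
  }
  comm <- match(lab, unique(lab))
  intra <- tapply(w[lab[e[, 1L]] == lab[e[, 2L]]],
                  comm[e[, 1L]][lab[e[, 1L]] == lab[e[, 2L]]], sum)
  wc <- numeric(max(comm))
  if (length(intra)) wc[as.integer(names(intra))] <- intra
  sc <- tapply(strength, comm, sum)
  sum(wc / m) - sum((sc / (2 * m))^2)
}

## evaluate expr with a locally fixed RNG state, restoring afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Louvain modularity parcellation
#'
#' Partitions the weighted voxel lattice into modules of coherent voxels by
#' greedy two-phase Louvain modularity optimization (local moves from a
#' singleton initialization, then graph coarsening, repeated to
#' convergence). The modules are the per-timepoint ROIs (iROIs). Because no
#' lattice edge crosses a meta-region boundary, no module ever spans two
#' meta-regions. Louvain's node visit order is randomized; a fixed `seed`
#' makes runs reproducible. Degree-0 voxels become singleton modules.
#'
#' @param graph a `lattice_graph`, usually coherence-weighted.
#' @param seed integer seed for the (randomized) optimization.
#' @param resolution resolution parameter of the modularity objective;
#'   1.0 is plain modularity.
#' @return A [parcellation()] with provenance `"iROI"` and dense integer
#'   labels.
#' @export
louvain_partition <- function(graph, seed = 1L, resolution = 1.0) {
  stopifnot(inherits(graph, "lattice_graph"))
  if (length(graph$voxels) == 0L) stop("graph is empty")
  g <- as_igraph(graph)
  memb <- with_local_seed(seed, {
    cl <- igraph::cluster_louvain(g, resolution = resolution)
    igraph::membership(cl)
  })
  parcellation(as.integer(memb), graph$voxels, provenance = "iROI")
}
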