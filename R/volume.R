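#' Voxel grid with mask and meta-region membership
#'
#' A `volume_grid` couples a binary gray-matter mask with an integer
#' meta-region atlas on the same 3D raster. Meta-regions are coarse
#' anatomical territories that constrain which voxels may ever share a
#' lattice edge (and hence an ROI): no edge is drawn across a meta-region
#' boundary.
#'
#' @param mask logical 3D array; `TRUE` marks in-mask (analyzed) voxels.
#' @param atlas integer 3D array of the same dimensions; meta-region ID per
#'   voxel, with 0 outside the mask. Must be strictly positive exactly where
#'   `mask` is `TRUE`.
#' @return An object of class `volume_grid` with fields `dims`, `mask`,
#'   `meta`.
#' @export
volume_grid <- function(mask, atlas) {
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("'mask' must be a logical 3D array")
  if (!identical(dim(mask), dim(atlas)))
    stop("'mask' and 'atlas' dimensions differ")
  atlas <- array(as.integer(atlas), dim = dim(atlas))
  if (!all((atlas > 0L) == mask))
    stop("'atlas' must be positive exactly where 'mask' is TRUE (0 elsewhere)")
  if (!any(mask))
    stop("mask is empty: no in-mask voxels")
  structure(list(dims = dim(mask), mask = mask, meta = atlas),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("volume_grid: %s grid, %d in-mask voxels, %d meta-regions\n",
              paste(x$dims, collapse = "x"), sum(x$mask),
              length(unique(x$meta[x$mask]))))
  invisible(x)
}

#' Binarize a probability volume
#'
#' Converts a tissue-probability (or any real-valued) volume to a binary
#' mask. A voxel is retained iff its value strictly exceeds `threshold`;
#' a value equal to the threshold is excluded.
#'
#' @param probability_volume real 3D array with finite values.
#' @param threshold scalar cut-off, default 0.5.
#' @return logical 3D array.
#' @export
binarize_mask <- function(probability_volume, threshold = 0.5) {
  if (!all(is.finite(probability_volume)))
    stop("'probability_volume' contains non-finite values")
  out <- probability_volume > threshold
  if (!any(out))
    stop("binarized mask is empty (no voxel exceeds the threshold)")
  out
}

## linear index (column-major, 1-based) -> integer voxel coordinates
voxel_coords <- function(idx, dims) arrayInd(idx, .dim = dims)

## 6-neighborhood (face adjacency) of linear indices; returns a matrix with
## columns 'from' (linear idx) and 'to' (linear idx), clipped at grid edges
face_neighbors <- function(idx, dims) {
  co <- voxel_coords(idx, dims)
  out_from <- integer(0)
  out_to <- integer(0)
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  for (ax in 1:3) {
    for (dir in c(-1L, 1L)) {
      ok <- if (dir == 1L) co[, ax] < dims[ax] else co[, ax] > 1L
      out_from <- c(out_from, idx[ok])
      out_to <- c(out_to, idx[ok] + dir * strides[ax])
    }
  }
  cbind(from = out_from, to = out_to)
}

## is the voxel set (linear indices) connected under 6-adjacency?
is_connected_6 <- function(idx, dims) {
  if (length(idx) <= 1L) return(TRUE)
  member <- logical(prod(dims))
  member[idx] <- TRUE
  seen <- logical(prod(dims))
  frontier <- idx[1L]
  seen[frontier] <- TRUE
  while (length(frontier)) {
    nb <- face_neighbors(frontier, dims)
    nxt <- unique(nb[, "to"][member[nb[, "to"]] & !seen[nb[, "to"]]])
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  sum(seen) == length(idx)
}

#' Voxel graph container
#'
#' Holds a set of voxel nodes (linear indices into the raster, sorted
#' ascending) and an undirected edge list between node positions, with an
#' optional nonnegative weight per edge. [build_lattice()] produces the
#' anatomically constrained 6-connectivity lattice; the constructor also
#' accepts arbitrary graphs (with `dims = NULL`) for abstract fixtures.
#'
#' @param voxels integer vector of voxel linear indices (node identities).
#' @param edges two-column integer matrix of node positions (indices into
#'   `voxels`), each row one undirected edge with `edges[,1] < edges[,2]`.
#' @param weights optional numeric vector of nonnegative edge weights.
#' @param dims optional grid dimensions; when given, every edge is checked
#'   to join face-adjacent voxels.
#' @return An object of class `lattice_graph`.
#' @export
lattice_graph <- function(voxels, edges, weights = NULL, dims = NULL) {
  voxels <- as.integer(voxels)
  if (is.null(edges) || length(edges) == 0L)
    edges <- matrix(integer(0), ncol = 2L)
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges)) {
    if (any(edges < 1L) || any(edges > length(voxels)))
      stop("edge endpoints out of range")
    if (any(edges[, 1L] >= edges[, 2L]))
      stop("edges must satisfy edges[,1] < edges[,2] (undirected, no self-loops)")
  }
  if (!is.null(weights)) {
    if (length(weights) != nrow(edges)) stop("one weight per edge required")
    if (any(!is.finite(weights)) || any(weights < 0))
      stop("weights must be finite and nonnegative")
  }
  if (!is.null(dims) && nrow(edges)) {
    d <- abs(voxel_coords(voxels[edges[, 1L]], dims) -
             voxel_coords(voxels[edges[, 2L]], dims))
    if (!all(rowSums(d) == 1L))
      stop("edges must join face-adjacent voxels (exactly one axis differs by 1)")
  }
  structure(list(voxels = voxels, edges = edges, weights = weights,
                 dims = dims),
            class = "lattice_graph")
}

#' @export
print.lattice_graph <- function(x, ...) {
  cat(sprintf("lattice_graph: n = %d voxels, m = %d edges (%s)\n",
              length(x$voxels), nrow(x$edges),
              if (is.null(x$weights)) "unweighted" else "weighted"))
  invisible(x)
}

#' Build the anatomically constrained voxel lattice
#'
#' Creates the graph G = (V, E) whose nodes are the in-mask voxels and whose
#' edges join each voxel to its face-sharing 6-neighbors, restricted to
#' pairs lying inside the same meta-region. Node order is ascending linear
#' index (lexicographic in x, y, z with x fastest); edges are sorted
#' lexicographically.
#'
#' @param grid a [volume_grid()].
#' @return An unweighted `lattice_graph`.
#' @export
build_lattice <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  vox <- which(grid$mask)              # sorted ascending
  dims <- grid$dims
  strides <- c(1L, dims[1L], dims[1L] * dims[2L])
  co <- voxel_coords(vox, dims)
  from <- integer(0); to <- integer(0)
  for (ax in 1:3) {                    # +1 direction only: each pair once
    ok <- co[, ax] < dims[ax]
    f <- vox[ok]
    t_ <- f + strides[ax]
    keep <- grid$mask[t_] & grid$meta[f] == grid$meta[t_]
    from <- c(from, f[keep]); to <- c(to, t_[keep])
  }
  pos <- match(from, vox); qos <- match(to, vox)
  lo <- pmin(pos, qos); hi <- pmax(pos, qos)
  o <- order(lo, hi)
  lattice_graph(vox, cbind(lo, hi)[o, , drop = FALSE], dims = dims)
}

## degree (edge count) per node position
node_degree <- function(graph) {
  deg <- integer(length(graph$voxels))
  if (nrow(graph$edges)) {
    t1 <- tabulate(graph$edges[, 1L], nbins = length(graph$voxels))
    t2 <- tabulate(graph$edges[, 2L], nbins = length(graph$voxels))
    deg <- t1 + t2
  }
  deg
}

## adjacency as list of neighbor node positions
neighbor_list <- function(graph) {
  n <- length(graph$voxels)
  nl <- vector("list", n)
  for (i in seq_len(n)) nl[[i]] <- integer(0)
  if (nrow(graph$edges)) {
    e <- graph$edges
    nl <- split(c(e[, 2L], e[, 1L]), factor(c(e[, 1L], e[, 2L]), levels = seq_len(n)))
    nl <- unname(lapply(nl, as.integer))
  }
  nl
}

## lattice_graph -> igraph object (weights attached if present)
as_igraph <- function(graph) {
  g <- igraph::make_empty_graph(n = length(graph$voxels), directed = FALSE)
  if (nrow(graph$edges)) {
    g <- igraph::add_edges(g, as.vector(t(graph$edges)))
    if (!is.null(graph$weights))
      igraph::E(g)$weight <- graph$weights
  }
  g
}
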