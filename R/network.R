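#' Mean time series per ROI
#'
#' Averages the BOLD series over the voxels of each module, giving one
#' representative series per ROI (unweighted voxel mean at each time index).
#'
#' @param bold 4D numeric array (x, y, z, t).
#' @param part a [parcellation()] over voxels of that grid.
#' @return numeric matrix, one row per ROI (rownames = label IDs, ascending)
#'   and one column per time point.
#' @export
roi_mean_series <- function(bold, part) {
  stopifnot(inherits(part, "parcellation"))
  dims <- dim(bold)
  if (length(dims) != 4L) stop("'bold' must be a 4D array (x, y, z, t)")
  if (max(part$voxels) > prod(dims[1:3]))
    stop("parcellation voxel indices exceed the bold grid")
  M <- matrix(bold, ncol = dims[4L])
  S <- rowsum(M[part$voxels, , drop = FALSE], group = part$labels)
  cnt <- rowsum(rep(1, length(part$labels)), group = part$labels)
  S / as.vector(cnt)                      # rows in ascending label order
}

#' FDR-thresholded ROI correlation network
#'
#' Computes all pairwise Pearson correlations between ROI mean series,
#' derives two-sided p-values from the t approximation with T - 2 degrees of
#' freedom, applies Benjamini-Hochberg false-discovery-rate control over the
#' n(n-1)/2 tests, and joins the surviving pairs by a weighted link carrying
#' the (signed) correlation value.
#'
#' ROIs with constant series have undefined correlations; their pairs are
#' excluded from testing with a warning. No autocorrelation correction is
#' applied to the p-values.
#'
#' @param ts ROI-by-time numeric matrix (at least 2 ROIs, 3 time points).
#' @param alpha FDR level, default 0.05.
#' @param positive_only if `TRUE`, discard surviving edges with negative
#'   correlation. Default `FALSE`: signed weights are kept (binary metrics
#'   ignore sign regardless).
#' @return An object of class `roi_network`: list with `roi_ids`, symmetric
#'   `weights` matrix (zero diagonal; 0 = no link), and logical `binary`
#'   adjacency.
#' @export
correlation_network <- function(ts, alpha = 0.05, positive_only = FALSE) {
  ts <- as.matrix(ts)
  n <- nrow(ts); nt <- ncol(ts)
  if (n < 2L) stop("need at least 2 ROIs")
  if (nt < 3L) stop("need at least 3 time samples")
  roi_ids <- rownames(ts)
  if (is.null(roi_ids)) roi_ids <- as.character(seq_len(n))
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0))
    warning("excluding ", sum(sds == 0),
            " constant ROI series from correlation testing (r undefined)",
            call. = FALSE)
  R <- suppressWarnings(stats::cor(t(ts)))
  ut <- which(upper.tri(R), arr.ind = TRUE)
  valid <- sds[ut[, 1L]] > 0 & sds[ut[, 2L]] > 0
  r <- R[ut]
  p <- rep(NA_real_, length(r))
  df <- nt - 2L
  rr <- pmin(pmax(r[valid], -1), 1)
  tstat <- rr * sqrt(df / pmax(1 - rr^2, .Machine$double.eps))
  p[valid] <- 2 * stats::pt(-abs(tstat), df = df)
  padj <- rep(NA_real_, length(p))
  padj[valid] <- stats::p.adjust(p[valid], method = "BH")
  keep <- !is.na(padj) & padj <= alpha
  if (positive_only) keep <- keep & r > 0
  W <- matrix(0, n, n, dimnames = list(roi_ids, roi_ids))
  if (any(keep)) {
    W[ut[keep, , drop = FALSE]] <- r[keep]
    W[ut[keep, c(2L, 1L), drop = FALSE]] <- r[keep]
  }
  structure(list(roi_ids = roi_ids, weights = W, binary = W != 0),
            class = "roi_network")
}

#' @export
print.roi_network <- function(x, ...) {
  cat(sprintf("roi_network: %d ROIs, %d links, total strength %.3f\n",
              length(x$roi_ids), count_links(x), total_strength(x)))
  invisible(x)
}

#' Global network metrics
#'
#' `count_links()` returns the number of surviving (unordered) ROI pairs;
#' `total_strength()` the sum of their signed weights.
#'
#' @param net a [correlation_network()] result.
#' @return scalar.
#' @export
count_links <- function(net) {
  stopifnot(inherits(net, "roi_network"))
  sum(net$binary[upper.tri(net$binary)])
}

#' @rdname count_links
#' @export
total_strength <- function(net) {
  stopifnot(inherits(net, "roi_network"))
  sum(net$weights[upper.tri(net$weights)])
}

binary_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(net$binary * 1, mode = "undirected",
                                      diag = FALSE)
}

#' Mean clustering coefficient
#'
#' Average over all nodes of the binary local clustering coefficient
#' \eqn{C_i = 2 |\{e_{jk} : j,k \in N_i, e_{jk} \in E\}| / k_i (k_i - 1)},
#' the fraction of a node's neighbor pairs that are themselves linked.
#' Nodes with degree below 2 (where the ratio is 0/0) contribute
#' \eqn{C_i = 0}.
#'
#' @param net a [correlation_network()] result; computed on the binary
#'   adjacency.
#' @return scalar in \[0, 1\].
#' @export
mean_clustering <- function(net) {
  stopifnot(inherits(net, "roi_network"))
  ci <- igraph::transitivity(binary_igraph(net), type = "localundirected",
                             isolates = "zero")
  mean(ci)
}

#' Mean shortest path length
#'
#' Characteristic path length
#' \eqn{l_G = \frac{1}{n(n-1)} \sum_{i \ne j} d(i, j)} over the binary
#' adjacency, with \eqn{d(i,j)} the number of edges on the shortest path.
#' If the graph is disconnected, unreachable ordered pairs are excluded
#' from both numerator and denominator and the returned value carries
#' attribute `disconnected = TRUE`.
#'
#' @param net a [correlation_network()] result.
#' @return scalar (mean over reachable ordered pairs), with logical
#'   attribute `"disconnected"`.
#' @export
mean_path_length <- function(net) {
  stopifnot(inherits(net, "roi_network"))
  d <- igraph::distances(binary_igraph(net))
  offdiag <- d[row(d) != col(d)]
  finite <- offdiag[is.finite(offdiag)]
  if (!length(finite))
    stop("no finite node pairs: path length undefined on an edgeless graph")
  structure(mean(finite), disconnected = any(!is.finite(offdiag)))
}
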