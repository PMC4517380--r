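# Shared fixtures and independent brute-force oracles. Oracles deliberately
# use naive enumeration so they share no code path with the implementation.

two_triangles <- function(weights = NULL) {
  lattice_graph(voxels = 1:6,
                edges = rbind(c(1L, 2L), c(1L, 3L), c(2L, 3L),
                              c(4L, 5L), c(4L, 6L), c(5L, 6L)),
                weights = weights)
}

# dense adjacency matrix of a lattice_graph
dense_adjacency <- function(graph) {
  n <- length(graph$voxels)
  A <- matrix(0, n, n)
  w <- if (is.null(graph$weights)) rep(1, nrow(graph$edges)) else graph$weights
  for (r in seq_len(nrow(graph$edges))) {
    i <- graph$edges[r, 1L]; j <- graph$edges[r, 2L]
    A[i, j] <- A[i, j] + w[r]; A[j, i] <- A[j, i] + w[r]
  }
  A
}

# double-loop evaluation of Q = 1/2m sum_ij (A_ij - k_i k_j / 2m) d(C_i,C_j)
brute_modularity <- function(graph, labels) {
  A <- dense_adjacency(graph)
  k <- rowSums(A)
  two_m <- sum(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (labels[i] == labels[j]) q <- q + A[i, j] - k[i] * k[j] / two_m
  q / two_m
}

# all-pairs brute-force lattice: every in-mask pair at L1 distance 1 within
# one meta-region
brute_lattice_edges <- function(grid) {
  vox <- which(grid$mask)
  co <- arrayInd(vox, .dim = grid$dims)
  out <- NULL
  for (a in seq_along(vox)) for (b in seq_along(vox)) {
    if (a >= b) next
    if (sum(abs(co[a, ] - co[b, ])) == 1L &&
        grid$meta[vox[a]] == grid$meta[vox[b]])
      out <- rbind(out, c(a, b))
  }
  if (is.null(out)) matrix(integer(0), ncol = 2L) else out
}

random_grid <- function(dims, n_regions, seed) {
  set.seed(seed)
  mask <- array(runif(prod(dims)) < 0.7, dims)
  if (!any(mask)) mask[1] <- TRUE
  atlas <- array(0L, dims)
  atlas[mask] <- sample.int(n_regions, sum(mask), replace = TRUE)
  volume_grid(mask, atlas)
}

# random abstract weighted graph as lattice_graph (dims = NULL)
random_graph <- function(n, p = 0.3, weighted = TRUE, seed = 1) {
  set.seed(seed)
  pairs <- t(combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  e <- pairs[keep, , drop = FALSE]
  w <- if (weighted && nrow(e)) runif(nrow(e), 0.1, 2) else NULL
  lattice_graph(voxels = seq_len(n), edges = e, weights = w)
}

# binary adjacency oracles ---------------------------------------------------

brute_mean_clustering <- function(A) {
  n <- nrow(A)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in nb) for (b in nb) if (a < b && A[a, b] != 0) links <- links + 1
    ci[i] <- 2 * links / (k * (k - 1))
  }
  mean(ci)
}

brute_mean_path_length <- function(A) {
  n <- nrow(A)
  D <- ifelse(A != 0, 1, Inf)
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

comembership <- function(labels) outer(labels, labels, "==")

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# standard perturbed phantom pipeline, computed once per test run ------------

.fixture_cache <- new.env(parent = emptyenv())

standard_ailp <- function() {
  if (!is.null(.fixture_cache$std)) return(.fixture_cache$std)
  ph <- generate_phantom(phantom_spec(seed = 11L))
  grid <- volume_grid(ph$mask, ph$atlas)
  lat <- build_lattice(grid)
  w1 <- weight_lattice(lat, ph$bold_t1)
  w2 <- weight_lattice(lat, ph$bold_t2)
  p1 <- louvain_partition(w1, seed = 1L)
  p2 <- louvain_partition(w2, seed = 2L)
  agg <- aggregate_parcellations(p1, p2)
  lp <- ailp(lat, p1, p2, seed = 1L)
  .fixture_cache$std <- list(ph = ph, grid = grid, lattice = lat,
                             w1 = w1, w2 = w2, p1 = p1, p2 = p2,
                             agg = agg, lp = lp)
  .fixture_cache$std
}

# tiny one-region two-block phantom whose blocks Louvain recovers exactly
recovery_phantom <- function(noise_sd = 0) {
  generate_phantom(phantom_spec(grid_dims = c(2L, 4L, 2L),
                                n_meta_regions = 1L, blocks_per_region = 2L,
                                noise_sd = noise_sd,
                                perturbation_fraction = 0, seed = 7L))
}

run_full_pipeline_in_memory <- function(ph, louvain_seed = 1L, lp_seed = 1L) {
  grid <- volume_grid(ph$mask, ph$atlas)
  lat <- build_lattice(grid)
  p1 <- louvain_partition(weight_lattice(lat, ph$bold_t1), seed = louvain_seed)
  p2 <- louvain_partition(weight_lattice(lat, ph$bold_t2),
                          seed = louvain_seed + 1L)
  list(grid = grid, lattice = lat, p1 = p1, p2 = p2,
       lp = ailp(lat, p1, p2, seed = lp_seed))
}
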