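test_that("modularity matches hand-computed fixtures", {
  tri <- two_triangles()
  part_tri <- parcellation(c(1, 1, 1, 2, 2, 2), 1:6, "truth")
  expect_equal(modularity_score(tri, part_tri), 0.5)
  # all-in-one partition always scores 0
  expect_equal(modularity_score(tri, parcellation(rep(1, 6), 1:6, "truth")), 0)
  # invariant under label bijection
  relab <- parcellation(c(7, 7, 7, 3, 3, 3), 1:6, "truth")
  expect_equal(modularity_score(tri, relab), 0.5)
  # weighted variant still integrates weights
  triw <- two_triangles(weights = c(2, 2, 2, 1, 1, 1))
  expect_equal(modularity_score(triw, part_tri),
               brute_modularity(triw, part_tri$labels))
  # zero-weight graph is rejected
  empty <- lattice_graph(1:3, NULL)
  expect_error(modularity_score(empty, parcellation(1:3, 1:3, "truth")),
               "zero total")
})

test_that("modularity agrees with the double-loop oracle on random graphs", {
  for (s in 1:100) {
    n <- sample(5:30, 1)
    g <- random_graph(n, p = 0.3, weighted = (s %% 2 == 0), seed = 2000 + s)
    if (nrow(g$edges) == 0) next
    labs <- sample.int(max(2L, n %/% 3L), n, replace = TRUE)
    part <- parcellation(labs, seq_len(n), "truth")
    expect_equal(modularity_score(g, part), brute_modularity(g, labs),
                 tolerance = 1e-10)
    expect_equal(modularity_score(g, parcellation(rep(1L, n), seq_len(n),
                                                  "truth")), 0,
                 tolerance = 1e-12)
  }
})

test_that("Louvain recovers planted structure and is seed-deterministic", {
  tri <- two_triangles()
  p <- louvain_partition(tri, seed = 1L)
  expect_equal(length(unique(p$labels)), 2L)
  expect_equal(modularity_score(tri, p), 0.5)
  expect_identical(p$labels, louvain_partition(tri, seed = 1L)$labels)

  # single edge: merged endpoints (Q = 0) beat the split (Q = -0.5)
  single <- lattice_graph(1:2, rbind(c(1L, 2L)))
  expect_length(unique(louvain_partition(single, seed = 1L)$labels), 1L)

  # noiseless one-region two-block phantom: exact recovery
  ph <- recovery_phantom(noise_sd = 0)
  lat <- build_lattice(volume_grid(ph$mask, ph$atlas))
  p1 <- louvain_partition(weight_lattice(lat, ph$bold_t1), seed = 1L)
  expect_equal(ari(p1$labels, ph$truth_t1$labels), 1)
})

test_that("Louvain never scores below the singleton baseline", {
  for (s in 1:5) {
    g <- random_graph(20, p = 0.2, weighted = TRUE, seed = 3000 + s)
    if (nrow(g$edges) == 0) next
    p <- louvain_partition(g, seed = s)
    singletons <- parcellation(seq_along(g$voxels), g$voxels, "truth")
    expect_gte(modularity_score(g, p),
               modularity_score(g, singletons))
  }
})

test_that("per-meta-region runs match the whole-graph run on clean data", {
  # regions sized so modularity's resolution limit bites neither jointly
  # nor alone (Q's null term depends on the global edge weight, so
  # per-region decomposability is only approximate in general)
  ph <- generate_phantom(phantom_spec(grid_dims = c(4L, 4L, 2L),
                                      n_meta_regions = 2L,
                                      blocks_per_region = 2L,
                                      noise_sd = 0, perturbation_fraction = 0,
                                      seed = 7L))
  grid <- volume_grid(ph$mask, ph$atlas)
  whole <- louvain_partition(weight_lattice(build_lattice(grid), ph$bold_t1),
                             seed = 1L)
  for (r in unique(ph$atlas[ph$mask])) {
    sub_mask <- ph$mask & ph$atlas == r
    sub_grid <- volume_grid(sub_mask, array(ifelse(sub_mask, r, 0L),
                                            dim = dim(sub_mask)))
    sub <- louvain_partition(weight_lattice(build_lattice(sub_grid),
                                            ph$bold_t1), seed = 1L)
    sel <- grid$meta[whole$voxels] == r
    expect_gte(ari(whole$labels[sel], sub$labels), 0.95)
  }
})
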