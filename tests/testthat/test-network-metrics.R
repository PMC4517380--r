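test_that("ROI mean series average voxel series per module", {
  nt <- 20L
  set.seed(5)
  bold <- array(rnorm(4 * nt), c(4, 1, 1, nt))
  part <- parcellation(c(1L, 1L, 2L, 3L), 1:4, "lpROI")
  ts <- roi_mean_series(bold, part)
  expect_equal(ts["1", ], (bold[1, 1, 1, ] + bold[2, 1, 1, ]) / 2,
               ignore_attr = TRUE)
  expect_equal(ts["3", ], bold[4, 1, 1, ], ignore_attr = TRUE)
  # opposite series cancel
  bold[2, 1, 1, ] <- -bold[1, 1, 1, ]
  expect_equal(unname(roi_mean_series(bold, part)["1", ]), rep(0, nt))
  # noiseless phantom block mean reproduces the source
  ph <- recovery_phantom(noise_sd = 0)
  ts2 <- roi_mean_series(ph$bold_t1, ph$truth_t1)
  v <- ph$truth_t1$voxels[ph$truth_t1$labels == 1L][1]
  expect_equal(unname(ts2["1", ]), ph$bold_t1[arrayInd(v, dim(ph$mask))[1],
                                              arrayInd(v, dim(ph$mask))[2],
                                              arrayInd(v, dim(ph$mask))[3], ])
})

test_that("correlation network keeps exactly the significant pairs", {
  set.seed(6)
  nt <- 60L
  s <- rnorm(nt)
  # identical series: r = 1, survives
  net <- correlation_network(rbind(a = s, b = s))
  expect_equal(count_links(net), 1L)
  expect_equal(total_strength(net), 1)
  # two copies of a signal plus independent noise: only the (1,2) edge
  ts <- rbind(a = s + 0.2 * rnorm(nt), b = s + 0.2 * rnorm(nt),
              c = rnorm(nt))
  net2 <- correlation_network(ts)
  expect_true(net2$binary["a", "b"])
  expect_false(net2$binary["a", "c"])
  expect_false(net2$binary["b", "c"])
  # Pearson invariance under per-ROI affine rescaling
  ts3 <- ts * c(2, -3, 0.5) + c(10, -4, 0)
  net3 <- correlation_network(ts3)
  expect_identical(net3$binary, net2$binary)
  # symmetry, zero diagonal, binary consistent with weights
  expect_identical(net2$weights, t(net2$weights))
  expect_equal(diag(net2$weights), c(a = 0, b = 0, c = 0))
  expect_identical(net2$binary, net2$weights != 0)
})

test_that("constant ROI series are excluded with a warning", {
  set.seed(7)
  ts <- rbind(a = rnorm(30), b = rnorm(30), c = rep(1, 30))
  expect_warning(net <- correlation_network(ts), "constant")
  expect_false(any(net$binary["c", ]))
})

test_that("link count and strength sum surviving edges", {
  W <- matrix(0, 4, 4, dimnames = rep(list(letters[1:4]), 2))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["c", "d"] <- W["d", "c"] <- 0.25
  net <- structure(list(roi_ids = letters[1:4], weights = W,
                        binary = W != 0), class = "roi_network")
  expect_equal(count_links(net), 2L)
  expect_equal(total_strength(net), 0.75)
  Wc <- matrix(1, 4, 4) - diag(4)
  full <- structure(list(roi_ids = 1:4, weights = Wc, binary = Wc != 0),
                    class = "roi_network")
  expect_equal(count_links(full), 6L)        # C(4,2)
  expect_equal(total_strength(full), 6)
  expect_equal(mean_path_length(full), 1, ignore_attr = TRUE)
  expect_equal(mean_clustering(full), 1)
})

as_net <- function(A) {
  structure(list(roi_ids = seq_len(nrow(A)), weights = A, binary = A != 0),
            class = "roi_network")
}

test_that("clustering and path length match hand-computed fixtures", {
  tri <- matrix(0, 3, 3); tri[cbind(c(1, 1, 2), c(2, 3, 3))] <- 1
  tri <- tri + t(tri)
  expect_equal(mean_clustering(as_net(tri)), 1)
  path3 <- matrix(0, 3, 3); path3[cbind(c(1, 2), c(2, 3))] <- 1
  path3 <- path3 + t(path3)
  expect_equal(mean_clustering(as_net(path3)), 0)
  expect_equal(mean_path_length(as_net(path3)), 4 / 3, ignore_attr = TRUE)
  # triangle plus pendant: C = (1 + 1 + 1/3 + 0)/4
  tp <- matrix(0, 4, 4)
  tp[cbind(c(1, 1, 2, 3), c(2, 3, 3, 4))] <- 1
  tp <- tp + t(tp)
  expect_equal(mean_clustering(as_net(tp)), (1 + 1 + 1 / 3 + 0) / 4)
  # two disconnected edges: within-component pairs only, flagged
  disc <- matrix(0, 4, 4)
  disc[cbind(c(1, 3), c(2, 4))] <- 1
  disc <- disc + t(disc)
  pl <- mean_path_length(as_net(disc))
  expect_equal(as.numeric(pl), 1)
  expect_true(attr(pl, "disconnected"))
  edgeless <- as_net(matrix(0, 3, 3))
  expect_error(mean_path_length(edgeless), "edgeless")
})

test_that("graph metrics agree with brute-force oracles on random graphs", {
  for (s in 1:100) {
    set.seed(5000 + s)
    n <- sample(4:25, 1)
    A <- matrix(0, n, n)
    up <- which(upper.tri(A))
    on <- up[runif(length(up)) < 0.25]
    A[on] <- 1
    A <- A + t(A)
    net <- as_net(A)
    expect_equal(mean_clustering(net), brute_mean_clustering(A),
                 tolerance = 1e-12)
    if (any(A != 0))
      expect_equal(as.numeric(mean_path_length(net)),
                   brute_mean_path_length(A), tolerance = 1e-12)
  }
})

test_that("BH thresholding controls false edges under the global null", {
  # small in-suite version; the full 50-replicate simulation runs in the
  # acceptance checks
  set.seed(8)
  fdp <- replicate(10, {
    ts <- matrix(rnorm(10 * 60), nrow = 10)
    net <- correlation_network(ts, alpha = 0.05)
    n_disc <- count_links(net)
    if (n_disc > 0) 1 else 0   # all nulls: every discovery is false
  })
  expect_lte(mean(fdp), 0.2)
})
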