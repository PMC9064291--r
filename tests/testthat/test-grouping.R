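test_that("well-separated clusters become groups; small clusters are singletons", {
  set.seed(2)
  c1 <- matrix(rep(c(2, 2, 2), each = 5), ncol = 3) +
    matrix(runif(15, 0, 0.5), ncol = 3)
  c2 <- matrix(rep(c(2, 2, 12), each = 5), ncol = 3) +
    matrix(runif(15, 0, 0.5), ncol = 3)
  spots <- make_spots(rbind(c1, c2))
  res <- cluster_groups(spots, linkage_cutoff_um = 2)
  expect_equal(nrow(res$groups), 2)
  expect_equal(sort(res$groups$size), c(5, 5))
  expect_length(res$singletons, 0)
  # lone spot 5 um from a 6-spot cluster -> 1 group + 1 singleton
  c3 <- matrix(rep(c(5, 5, 5), each = 6), ncol = 3) +
    matrix(runif(18, 0, 0.4), ncol = 3)
  spots2 <- make_spots(rbind(c3, c(5, 5, 10)))
  res2 <- cluster_groups(spots2, linkage_cutoff_um = 2)
  expect_equal(nrow(res2$groups), 1)
  expect_equal(res2$groups$size, 6)
  expect_length(res2$singletons, 1)
  expect_equal(res2$membership[7], -1L)
  expect_error(cluster_groups(spots, linkage_cutoff_um = -1), "positive")
})

test_that("group centroids and extents are consistent with membership", {
  set.seed(3)
  pos <- rbind(matrix(runif(12, 0, 1), ncol = 3),
               matrix(runif(9, 8, 9), ncol = 3))
  res <- cluster_groups(make_spots(pos), linkage_cutoff_um = 2)
  for (k in seq_len(nrow(res$groups))) {
    idx <- which(res$membership == res$groups$group_id[k])
    expect_equal(
      as.numeric(res$groups[k, c("centroid_z_um", "centroid_y_um",
                                 "centroid_x_um")]),
      colMeans(pos[idx, , drop = FALSE]), tolerance = 1e-9)
    expect_equal(res$groups$extent_um[k],
                 max(dist(pos[idx, , drop = FALSE])), tolerance = 1e-9)
  }
})

test_that("clustering equals the union-find oracle and is order-invariant", {
  set.seed(7)
  for (rep in 1:30) {
    n <- sample(2:40, 1)
    pos <- cbind(runif(n, 0, 12), runif(n, 0, 12), runif(n, 0, 12))
    cutoff <- runif(1, 0.5, 4)
    res <- cluster_groups(make_spots(pos), linkage_cutoff_um = cutoff,
                          min_group_size = 1L)
    oracle <- brute_force_single_linkage(pos, cutoff)
    expect_equal(canonical_partition(res$membership),
                 canonical_partition(oracle))
    # input order invariance
    perm <- sample(n)
    res_p <- cluster_groups(make_spots(pos[perm, ]),
                            linkage_cutoff_um = cutoff, min_group_size = 1L)
    expect_equal(canonical_partition(res_p$membership[order(perm)]),
                 canonical_partition(res$membership))
  }
})

test_that("partitions refine as the cutoff decreases", {
  set.seed(11)
  pos <- cbind(runif(25, 0, 8), runif(25, 0, 8), runif(25, 0, 8))
  big <- cluster_groups(make_spots(pos), linkage_cutoff_um = 3,
                        min_group_size = 1L)$membership
  small <- cluster_groups(make_spots(pos), linkage_cutoff_um = 1,
                          min_group_size = 1L)$membership
  # every fine cluster lies inside one coarse cluster
  for (g in unique(small))
    expect_length(unique(big[small == g]), 1)
})

test_that("lag is the arc distance from the projected centroid to the tip", {
  path <- cbind(c(10, 0), c(0, 0), c(0, 0))  # straight, tip at z = 0
  g <- list(group_id = 0, centroid_z_um = 6.32, centroid_y_um = 0.4,
            centroid_x_um = 0)
  lag <- measure_lag(g, path)
  expect_equal(lag$lag_um, 6.32, tolerance = 1e-9)
  g0 <- list(group_id = 1, centroid_z_um = 0, centroid_y_um = 0,
             centroid_x_um = 0)
  expect_equal(measure_lag(g0, path)$lag_um, 0)
  gfar <- list(group_id = 2, centroid_z_um = 5, centroid_y_um = 5,
               centroid_x_um = 0)
  expect_error(measure_lag(gfar, path), "tolerance")
})

test_that("lag is invariant under a rigid transformation of path and centroid", {
  set.seed(5)
  path <- cbind(seq(12, 0, length.out = 8),
                sin(seq(0, 1.5, length.out = 8)), rep(0, 8))
  q <- c(7.3, 0.6, 0.1)
  lag0 <- measure_lag(list(centroid_z_um = q[1], centroid_y_um = q[2],
                           centroid_x_um = q[3]), path)$lag_um
  # rotate about z-axis by 40 degrees, then translate
  th <- 40 * pi / 180
  Rm <- rbind(c(1, 0, 0), c(0, cos(th), -sin(th)), c(0, sin(th), cos(th)))
  shift <- c(3, -2, 5)
  path_r <- sweep(path %*% t(Rm), 2, shift, "+")
  q_r <- as.numeric(Rm %*% q + shift)
  lag1 <- measure_lag(list(centroid_z_um = q_r[1], centroid_y_um = q_r[2],
                           centroid_x_um = q_r[3]), path_r)$lag_um
  expect_equal(lag1, lag0, tolerance = 1e-9)
})

test_that("configured lag cohort reproduces the expected summary statistics", {
  # twelve dendrites with non-negative skewed lags scaled to mean 3.68,
  # SD 2.76 (deterministic gamma quantiles)
  shape <- (3.68 / 2.76)^2
  raw <- qgamma((seq_len(12) - 0.5) / 12, shape = shape,
                rate = shape / 3.68)
  lags <- (raw - mean(raw)) / sd(raw) * 2.76 + 3.68
  expect_true(all(lags > 0))
  measured <- vapply(lags, function(l) {
    path <- cbind(c(l + 5, 0), c(0, 0), c(0, 0))
    g <- list(centroid_z_um = l, centroid_y_um = 0.2, centroid_x_um = 0)
    measure_lag(g, path)$lag_um
  }, numeric(1))
  st <- summary_stats(measured)
  expect_equal(st$mean, 3.68, tolerance = 1e-9)
  expect_equal(round(st$sem, 2), 0.80)
})
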