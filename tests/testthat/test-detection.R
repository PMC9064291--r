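# Spot detection, counting, filament tracing and association, exercised
# against scenes whose ground truth is known exactly.

test_that("a noiseless single punctum is detected at its true position", {
  cfg <- scene_config(image_shape = c(24, 48, 48), knob_radius_um = 2,
                      min_separation_um = 1, snr = Inf, seed = 8)
  sc <- generate_knob_scene(cfg, 1, 0)
  spots <- detect_spots(sc$image)
  expect_equal(nrow(spots), 1)
  err <- sqrt(sum((as.numeric(spots[1, c("z_um", "y_um", "x_um")]) -
                   sc$truth$spot_positions_um[1, ])^2))
  expect_lt(err, 0.05)
})

test_that("an all-zero or missing channel is handled", {
  g <- voxel_grid(array(0, dim = c(12, 16, 16)), channel_names = "centrin")
  expect_equal(nrow(detect_spots(g)), 0)
  expect_error(detect_spots(g, channel = "nope"), "not found")
})

test_that("pure noise yields no detections at the default threshold", {
  hits <- vapply(1:20, function(s) {
    sc <- generate_knob_scene(
      scene_config(image_shape = c(20, 40, 40), seed = 1000 + s), 0, 0)
    nrow(detect_spots(sc$image))
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.95)
})

test_that("detection is equivariant to integer-voxel translation", {
  cfg <- scene_config(image_shape = c(28, 56, 56), knob_radius_um = 2,
                      min_separation_um = 1.2, seed = 31)
  sc <- generate_knob_scene(cfg, 6, 0)
  s0 <- detect_spots(sc$image)
  # shift the volume by whole voxels (2 in z, 4 in y, 4 in x)
  a <- sc$image$data
  b <- array(median(a), dim = dim(a))
  d <- dim(a)
  b[, , 3:d[3], 5:d[4], 5:d[5]] <- a[, , 1:(d[3] - 2), 1:(d[4] - 4),
                                     1:(d[5] - 4)]
  gb <- voxel_grid(array(b, dim = d), spacing_um = sc$image$spacing_um,
                   channel_names = sc$image$channel_names)
  s1 <- detect_spots(gb)
  expect_equal(nrow(s1), nrow(s0))
  shift <- c(2 * 0.27, 4 * 0.11, 4 * 0.11)
  p0 <- as.matrix(s0[, c("z_um", "y_um", "x_um")])
  p1 <- as.matrix(s1[, c("z_um", "y_um", "x_um")])
  # match shifted originals to translated detections
  for (i in seq_len(nrow(p0))) {
    dd <- sqrt(colSums((t(p1) - (p0[i, ] + shift))^2))
    expect_lt(min(dd), 0.15)
  }
})

test_that("spot count is monotone non-increasing in the absolute threshold", {
  cfg <- scene_config(image_shape = c(24, 48, 48), knob_radius_um = 2,
                      min_separation_um = 1.2, seed = 17)
  sc <- generate_knob_scene(cfg, 8, 0)
  thr <- seq(5, 400, length.out = 8)
  counts <- vapply(thr, function(tt)
    nrow(detect_spots(sc$image, threshold_policy = "absolute",
                      threshold_abs = tt)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("count_centrioles reports totals, per-roi counts and outside spots", {
  spots <- make_spots(rbind(c(1, 1, 1), c(1, 2, 2), c(3, 3, 3)))
  expect_equal(count_centrioles(spots)$total, 3)
  roi <- array(0L, dim = c(20, 40, 40))
  roi[1:16, 1:20, 1:20] <- 1L   # z <= 4.05 um, y/x <= 2.09 um
  res <- count_centrioles(spots, roi, spacing_um = c(0.27, 0.11, 0.11))
  expect_equal(res$per_roi$n, 2)   # third spot exceeds the y/x extent
  expect_equal(res$outside, 1)
  roi_all <- array(1L, dim = c(20, 40, 40))
  expect_equal(count_centrioles(spots, roi_all)$per_roi$n, 3)
  expect_equal(count_centrioles(make_spots(matrix(numeric(0), 0, 3)))$total, 0)
})

test_that("a straight rendered filament is traced with its true length", {
  cfg <- scene_config(image_shape = c(24, 64, 64), seed = 1)
  sp <- cfg$voxel_spacing_um
  d <- cfg$image_shape
  line <- cbind(rep(3, 2), c(1.5, 1.5), c(1, 6))  # 5 um along x
  tk <- centriolr:::tube_kernels(line, centriolr:::tube_sigma(cfg), 80)
  clean <- centriolr:::render_blobs(d, sp, tk$centers,
                                    centriolr:::tube_sigma(cfg), tk$amps)
  img <- array(clean + 50, dim = c(1, 1, d))
  g <- voxel_grid(img, spacing_um = sp, channel_names = "actub")
  cil <- detect_cilia(g, spot_channel = NULL)
  expect_equal(nrow(cil), 1)
  expect_equal(cil$length_um, 5, tolerance = 0.3)
})

test_that("filaments shorter than the minimum length are dropped", {
  cfg <- scene_config(image_shape = c(24, 48, 48), seed = 1)
  sp <- cfg$voxel_spacing_um
  d <- cfg$image_shape
  line <- cbind(rep(3, 2), c(2, 2), c(2, 3))  # 1 um
  tk <- centriolr:::tube_kernels(line, centriolr:::tube_sigma(cfg), 80)
  clean <- centriolr:::render_blobs(d, sp, tk$centers,
                                    centriolr:::tube_sigma(cfg), tk$amps)
  g <- voxel_grid(array(clean + 50, dim = c(1, 1, d)), spacing_um = sp,
                  channel_names = "actub")
  expect_equal(nrow(detect_cilia(g, min_length_um = 2,
                                 spot_channel = NULL)), 0)
})

test_that("association with perfect geometry reproduces the exact fraction", {
  set.seed(1)
  pos <- cbind(runif(36, 2, 10), runif(36, 2, 10), runif(36, 2, 10))
  spots <- make_spots(pos)
  bases <- pos[1:31, ] + matrix(rnorm(31 * 3, 0, 0.05), ncol = 3)
  cilia <- make_cilia(bases)
  res <- associate(spots, cilia, capture_radius_um = 0.5)
  expect_equal(res$fraction_associated, 31 / 36)
  expect_equal(nrow(res$pairs), 31)
  # no cilia: fraction 0
  expect_equal(associate(spots, cilia[0, ])$fraction_associated, 0)
  # relabeling ids leaves the fraction unchanged
  spots2 <- spots[rev(seq_len(nrow(spots))), ]
  spots2$id <- seq_len(nrow(spots2)) + 100L
  expect_equal(associate(spots2, cilia)$fraction_associated, 31 / 36)
})

test_that("assignment matching equals the exhaustive optimum on small instances", {
  set.seed(42)
  for (rep in 1:25) {
    ns <- sample(1:6, 1); nc <- sample(1:6, 1)
    spos <- cbind(runif(ns, 0, 4), runif(ns, 0, 4), runif(ns, 0, 4))
    cpos <- cbind(runif(nc, 0, 4), runif(nc, 0, 4), runif(nc, 0, 4))
    radius <- runif(1, 0.5, 3)
    res <- associate(make_spots(spos), make_cilia(cpos),
                     capture_radius_um = radius)
    cost <- matrix(Inf, ns, nc)
    for (j in seq_len(nc)) {
      dd <- sqrt(rowSums(sweep(spos, 2, cpos[j, ])^2))
      cost[dd <= radius, j] <- dd[dd <= radius]
    }
    oracle <- brute_force_assignment(cost)
    achieved <- -nrow(res$pairs) * 1e9 + sum(res$pairs$distance_um)
    if (is.infinite(oracle)) oracle <- 0  # no feasible pair anywhere
    if (nrow(res$pairs) == 0) achieved <- 0
    expect_equal(achieved, oracle, tolerance = 1e-9)
  }
})
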