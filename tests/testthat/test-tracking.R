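test_that("side-view projection takes the per-pixel maximum", {
  a <- array(0, dim = c(4, 4, 4))
  a[2, 3, 4] <- 7
  g <- voxel_grid(a)
  p <- project_side_view(g, axis = "x")
  expect_equal(dim(p$data), c(1, 1, 4, 4, 1))
  expect_equal(p$data[1, 1, 2, 3, 1], 7)
  # constant image projects to a constant
  gc <- voxel_grid(array(3, dim = c(4, 4, 4)))
  expect_true(all(project_side_view(gc, "y")$data == 3))
  # elementwise oracle on a random array
  set.seed(1)
  r <- array(runif(64), dim = c(4, 4, 4))
  gr <- voxel_grid(r)
  pr <- project_side_view(gr, "x")
  for (z in 1:4) for (y in 1:4)
    expect_equal(pr$data[1, 1, z, y, 1], max(r[z, y, ]))
  expect_error(project_side_view(g, axis = "z"), "apical")
})

test_that("the rate estimator is exact on noiseless constant-velocity tracks", {
  cfg <- scene_config(image_shape = c(80, 16, 16), snr = Inf, seed = 6)
  for (v in c(0.18, -0.07, 0)) {
    tl <- generate_timelapse(cfg, 1, v, n_frames = 7,
                             frame_interval_min = 12,
                             positional_noise_um = 0)
    tr <- link_tracks(truth_frame_groups(tl$truth),
                      tl$truth$frame_times_min)
    expect_equal(nrow(tr), 2)  # moving group + fiducial
    expect_equal(tr$rate_um_per_min[1], v, tolerance = 1e-9)
    expect_equal(tr$rate_um_per_min[1] * tr$elapsed_min[1],
                 tr$net_displacement_um[1], tolerance = 1e-9)
    expect_equal(tr$regression_rate_um_per_min[1], v, tolerance = 1e-9)
  }
})

test_that("a static fiducial cancels common drift", {
  cfg <- scene_config(image_shape = c(48, 16, 16), snr = Inf, seed = 7)
  tl <- generate_timelapse(cfg, 1, 0, n_frames = 6,
                           frame_interval_min = 10,
                           positional_noise_um = 0,
                           drift_um_per_min = c(0.05, 0, 0))
  tr_raw <- link_tracks(truth_frame_groups(tl$truth),
                        tl$truth$frame_times_min)
  expect_equal(abs(tr_raw$rate_um_per_min[1]), 0.05, tolerance = 1e-9)
  tr_fid <- link_tracks(truth_frame_groups(tl$truth),
                        tl$truth$frame_times_min,
                        fiducial_id = tl$truth$fiducial_index)
  expect_equal(tr_fid$rate_um_per_min[1], 0, tolerance = 1e-9)
})

test_that("rates and signs are recovered under jitter; linking is order-invariant", {
  cfg <- scene_config(image_shape = c(64, 48, 48), snr = Inf, seed = 8)
  vels <- c(0.1, -0.05, 0)
  tl <- generate_timelapse(cfg, 3, vels, n_frames = 10,
                           frame_interval_min = 10,
                           positional_noise_um = 0.05)
  pfg <- truth_frame_groups(tl$truth)
  tr <- link_tracks(pfg, tl$truth$frame_times_min,
                    fiducial_id = tl$truth$fiducial_index)
  expect_equal(nrow(tr), 4)
  # the set of recovered rates matches the configured velocities (plus the
  # static fiducial), each within +/- 0.02 um/min
  expect_equal(sort(tr$rate_um_per_min), sort(c(vels, 0)),
               tolerance = 0.02)
  # per-frame ordering of groups must not matter
  tr_plain <- link_tracks(pfg, tl$truth$frame_times_min)
  set.seed(99)
  pfg_shuf <- lapply(pfg, function(df) df[sample(nrow(df)), , drop = FALSE])
  tr2 <- link_tracks(pfg_shuf, tl$truth$frame_times_min)
  expect_equal(sort(tr2$rate_um_per_min), sort(tr_plain$rate_um_per_min),
               tolerance = 1e-9)
})

test_that("direction classification follows the displacement threshold", {
  expect_equal(classify_direction(list(net_displacement_um = 3)), "apical")
  expect_equal(classify_direction(list(net_displacement_um = -0.2)), "none")
  expect_equal(classify_direction(list(net_displacement_um = -1.2)), "basal")
  expect_equal(classify_direction(list(net_displacement_um = 0.4),
                                  displacement_threshold_um = 0.3), "apical")
})

test_that("a simulated cohort reproduces its apical fraction", {
  # 22 groups: 14 clearly apical, 8 basal-or-none
  set.seed(4)
  disp <- c(runif(14, 1, 5), runif(4, -3, -1), runif(4, -0.3, 0.3))
  labs <- vapply(disp, function(d)
    classify_direction(list(net_displacement_um = d)), character(1))
  expect_equal(sum(labs == "apical"), 14)
  expect_equal(sum(labs != "apical"), 8)
})

test_that("fiducial gaps are tolerated up to half the frames", {
  pfg <- lapply(1:6, function(f) data.frame(
    centroid_z_um = c(10 - 0.1 * f, 20), centroid_y_um = c(1, 1),
    centroid_x_um = c(1, 5)))
  # drop the fiducial from 4 of 6 frames
  pfg_miss <- pfg
  for (f in c(2, 3, 5, 6))
    pfg_miss[[f]] <- pfg_miss[[f]][1, , drop = FALSE]
  expect_error(link_tracks(pfg_miss, (0:5) * 10, fiducial_id = 2),
               "half the frames")
})

test_that("kymographs show the expected ridges", {
  cfg <- scene_config(image_shape = c(60, 40, 40), seed = 10)
  tl <- generate_timelapse(cfg, 1, 0.15, n_frames = 8,
                           frame_interval_min = 8,
                           positional_noise_um = 0.02)
  y0 <- tl$truth$track_centroids_um[1, 1, 2]
  line <- cbind(c(0.5, 15.5), c(y0, y0))
  km <- build_kymograph(tl$movie, line, width_um = 1)
  expect_equal(nrow(km$data), 8)
  slope <- kymograph_ridge_slope(km, tl$truth$frame_times_min)
  # arc runs basally (increasing z), so apical motion has negative slope
  expect_equal(slope, -0.15, tolerance = 0.15 * 0.1)
  # static group: vertical ridge
  tls <- generate_timelapse(cfg, 1, 0, n_frames = 6,
                            frame_interval_min = 8,
                            positional_noise_um = 0)
  ys <- tls$truth$track_centroids_um[1, 1, 2]
  kms <- build_kymograph(tls$movie, cbind(c(0.5, 15.5), c(ys, ys)),
                         width_um = 1)
  ridge <- kms$arc_um[apply(kms$data, 1, which.max)]
  expect_lt(max(ridge) - min(ridge), 0.12)
  # blank movie: kymograph stays at background
  blank <- voxel_grid(array(50, dim = c(3, 1, 20, 20, 8)),
                      channel_names = "centrin")
  kb <- build_kymograph(blank, cbind(c(0.5, 4.5), c(1, 1)), width_um = 0.5)
  expect_equal(as.vector(kb$data), rep(50, length(kb$data)))
  expect_error(build_kymograph(blank, cbind(c(0, 50), c(1, 1))), "bounds")
})
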