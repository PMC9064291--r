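# The synthetic generator defines the study conditions every downstream
# stage is tested against, so its own contracts are tested first.

small_cfg <- function(seed = 1, ...) {
  scene_config(image_shape = c(32, 96, 96), knob_radius_um = 2.5,
               min_separation_um = 1.2,
               cilium_length_range_um = c(2, 3), seed = seed, ...)
}

test_that("scene_config validates its invariants", {
  expect_error(scene_config(image_shape = c(4, 64, 64)), ">= 8")
  expect_error(scene_config(voxel_spacing_um = c(0.27, -0.1, 0.11)),
               "positive")
  expect_error(scene_config(snr = 0), "positive")
  expect_error(scene_config(expansion_factor = -1), "positive")
  expect_error(scene_config(cilium_length_range_um = c(5, 2)), "interval")
})

test_that("knob scenes are deterministic under a fixed seed, byte for byte", {
  s1 <- generate_knob_scene(small_cfg(seed = 11), 8, 5)
  s2 <- generate_knob_scene(small_cfg(seed = 11), 8, 5)
  expect_identical(s1$image$data, s2$image$data)
  expect_identical(s1$truth$spot_positions_um, s2$truth$spot_positions_um)
  expect_identical(s1$truth$cilium_curves, s2$truth$cilium_curves)
  s3 <- generate_knob_scene(small_cfg(seed = 12), 8, 5)
  expect_false(identical(s1$image$data, s3$image$data))
})

test_that("ground truth bookkeeping matches the requested scene", {
  sc <- generate_knob_scene(small_cfg(seed = 3), 10, 6)
  expect_equal(nrow(sc$truth$spot_positions_um), 10)
  expect_length(sc$truth$cilium_curves, 6)
  expect_length(sc$truth$cilium_to_spot, 6)
  # anchors are distinct puncta and each curve starts at its anchor
  expect_equal(anyDuplicated(sc$truth$cilium_to_spot), 0L)
  for (k in seq_len(6)) {
    base <- sc$truth$cilium_curves[[k]][1, ]
    anchor <- sc$truth$spot_positions_um[sc$truth$cilium_to_spot[k], ]
    expect_lt(sqrt(sum((base - anchor)^2)), 1e-9)
  }
  # drawn lengths respect the configured range
  lens <- vapply(sc$truth$cilium_curves, polyline_length, numeric(1))
  expect_true(all(lens >= 2 - 1e-6 & lens <= 3 + 1e-6))
  # spacing respects the configured hard core
  d <- as.matrix(dist(sc$truth$spot_positions_um))
  diag(d) <- Inf
  expect_gte(min(d), 1.2)
})

test_that("asking for more cilia than centrioles is an error, empty is not", {
  expect_error(generate_knob_scene(small_cfg(), 5, 6), "exceed")
  sc <- generate_knob_scene(small_cfg(seed = 2), 0, 0)
  expect_equal(nrow(sc$truth$spot_positions_um), 0)
  # pure background: no structure above the noise floor
  expect_lt(max(sc$image$data) - mean(sc$image$data),
            8 * sd(sc$image$data))
})

test_that("noiseless render equals signal plus background; noise adds variance", {
  cfg0 <- small_cfg(seed = 4, snr = Inf)
  sc0 <- generate_knob_scene(cfg0, 1, 0)
  # single punctum: intensity-weighted centroid equals the true position
  vol <- sc0$image$data[1, 1, , , ]
  vol <- vol - min(vol)
  d <- dim(vol)
  sp <- cfg0$voxel_spacing_um
  w <- vol / sum(vol)
  cz <- sum((slice.index(vol, 1) - 1) * sp[1] * w)
  cy <- sum((slice.index(vol, 2) - 1) * sp[2] * w)
  cx <- sum((slice.index(vol, 3) - 1) * sp[3] * w)
  expect_lt(sqrt(sum((c(cz, cy, cx) -
                      sc0$truth$spot_positions_um[1, ])^2)), 0.01)
  # identical geometry with noise: background variance strictly positive
  scn <- generate_knob_scene(small_cfg(seed = 4), 1, 0)
  expect_gt(var(as.vector(scn$image$data[1, 1, 1:4, , ])), 0)
})

test_that("time-lapse truth obeys the configured kinematics", {
  cfg <- scene_config(image_shape = c(80, 24, 24), snr = Inf, seed = 5)
  tl <- generate_timelapse(cfg, 1, +0.18, n_frames = 10,
                           frame_interval_min = 10,
                           positional_noise_um = 0)
  cent <- tl$truth$track_centroids_um
  # apical = decreasing z: displacement is +16.2 um apical over 90 min
  disp <- -(cent[10, 1, 1] - cent[1, 1, 1])
  expect_equal(disp, 0.18 * 90, tolerance = 1e-9)
  expect_equal(dim(tl$movie$data)[1], 10)
  # static group: identical centroid in every frame
  tl0 <- generate_timelapse(cfg, 1, 0, n_frames = 5,
                            frame_interval_min = 10,
                            positional_noise_um = 0)
  expect_equal(apply(tl0$truth$track_centroids_um[, 1, ], 2, var),
               c(0, 0, 0), tolerance = 1e-18)
  # the static fiducial is always appended
  expect_equal(tl$truth$fiducial_index, 2)
  expect_error(generate_timelapse(cfg, 2, 0.1, 5), "must equal")
  expect_error(generate_timelapse(cfg, 1, 1.5, 5), "sanity bound")
  expect_error(generate_timelapse(cfg, 1, 0.1, 1), ">= 2")
})

test_that("count tables are paired, Poisson-calibrated and deterministic", {
  ct <- generate_count_table(n_animals = 2, seed = 9)
  expect_equal(nrow(ct), 2 * 2 * 2 * 2)
  expect_true(all(table(ct$animal_id, ct$timepoint, ct$compartment) == 2))
  expect_equal(ct$normalized_per_100um, 100 * ct$count / ct$basal_length_um)
  expect_identical(ct, generate_count_table(n_animals = 2, seed = 9))
  expect_error(generate_count_table(timepoints = character(0)), "non-empty")
  # marginal calibration: >= 1000 draws within 3 SE of the configured mean
  big <- generate_count_table(n_animals = 1000, timepoints = "1h",
                              compartments = "subapical",
                              base_density_per_100um = 2.9,
                              length_um_range = c(1000, 1000), seed = 21)
  ctrl <- big$count[big$condition == "control"]
  expect_gte(length(ctrl), 1000)
  mu <- 2.9 * 1000 / 100
  se <- sqrt(mu / length(ctrl))
  expect_lt(abs(mean(ctrl) - mu), 3 * se)
  # configured multiplier scales the drug arm
  eff <- generate_count_table(
    n_animals = 200, timepoints = "6h", compartments = "subapical",
    drug_multiplier_by_compartment = list(subapical = 2.58),
    length_um_range = c(1000, 1000), seed = 22)
  ratio <- mean(eff$count[eff$condition == "drug"]) /
    mean(eff$count[eff$condition == "control"])
  expect_equal(ratio, 2.58, tolerance = 0.1)
})
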