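# Synthetic-scene generator. Produces images, time-lapses and count tables
# with known ground truth carrying the statistical structure the analysis
# assumes: dendritic knobs bearing diffraction-limited centriole puncta
# with attached filamentous cilia, 4D time-lapses of centriole groups
# moving along the apical axis beside a static fiducial, and paired
# drug/control count tables with configurable compartment enrichment.

#' Scene configuration for the synthetic generator
#'
#' Geometry is expressed in acquisition-frame micrometres (the expanded
#' gel for expansion-microscopy scenes). `psf_sigma_um` is the optical
#' point-spread function of the microscope in that frame; it is not scaled
#' by `expansion_factor`, which only converts reported lengths back to
#' biological (pre-expansion) units.
#'
#' @param image_shape integer vector, voxels per axis (z, y, x); all >= 8.
#' @param voxel_spacing_um micrometres per voxel for (z, y, x).
#' @param expansion_factor dimensionless gel expansion applied to physical
#'   structure sizes (reporting only).
#' @param psf_sigma_um Gaussian PSF sigma per axis (z, y, x), micrometres.
#' @param snr peak signal over background noise standard deviation; `Inf`
#'   disables noise entirely.
#' @param background_level mean background intensity (photon counts).
#' @param read_sigma Gaussian read-noise standard deviation.
#' @param seed mandatory RNG seed; generators never touch global RNG state.
#' @param knob_radius_um radius of the spherical dendritic-knob region.
#' @param min_separation_um minimum centriole centre-to-centre distance.
#' @param centriole_sigma_um apparent size (Gaussian sigma) of the
#'   centriole barrel before PSF blurring.
#' @param cilium_sigma_um Gaussian cross-section sigma of the ciliary
#'   axoneme before PSF blurring.
#' @param cilium_length_range_um min/max cilium arc length.
#' @param cilium_bend_frac control-point offset of the quadratic Bezier
#'   cilium backbone, as a fraction of its length.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(image_shape = c(64L, 160L, 160L),
                         voxel_spacing_um = c(0.27, 0.11, 0.11),
                         expansion_factor = 4,
                         psf_sigma_um = c(0.35, 0.15, 0.15),
                         snr = 10,
                         background_level = 50,
                         read_sigma = 3,
                         seed = 1L,
                         knob_radius_um = 4,
                         min_separation_um = 1.5,
                         centriole_sigma_um = 0.25,
                         cilium_sigma_um = 0.2,
                         cilium_length_range_um = c(2, 10),
                         cilium_bend_frac = 0.15) {
  image_shape <- as.integer(image_shape)
  if (length(image_shape) != 3L || any(image_shape < 8L))
    stop("'image_shape' must be 3 axis extents, all >= 8 voxels",
         call. = FALSE)
  assert_positive(voxel_spacing_um, "voxel_spacing_um")
  assert_positive(psf_sigma_um, "psf_sigma_um")
  assert_positive(expansion_factor, "expansion_factor")
  assert_positive(snr, "snr")
  assert_positive(knob_radius_um, "knob_radius_um")
  assert_positive(min_separation_um, "min_separation_um")
  if (background_level < 0 || read_sigma < 0)
    stop("'background_level' and 'read_sigma' must be non-negative",
         call. = FALSE)
  if (length(cilium_length_range_um) != 2L ||
      cilium_length_range_um[1] <= 0 ||
      diff(cilium_length_range_um) < 0)
    stop("'cilium_length_range_um' must be a positive increasing interval",
         call. = FALSE)
  structure(list(
    image_shape = image_shape,
    voxel_spacing_um = as.numeric(voxel_spacing_um),
    expansion_factor = expansion_factor,
    psf_sigma_um = as.numeric(psf_sigma_um),
    snr = snr, background_level = background_level, read_sigma = read_sigma,
    seed = as.integer(seed),
    knob_radius_um = knob_radius_um,
    min_separation_um = min_separation_um,
    centriole_sigma_um = centriole_sigma_um,
    cilium_sigma_um = cilium_sigma_um,
    cilium_length_range_um = as.numeric(cilium_length_range_um),
    cilium_bend_frac = cilium_bend_frac), class = "scene_config")
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config>\n")
  cat(sprintf("  shape (z,y,x): %s voxels; spacing %s um\n",
              paste(x$image_shape, collapse = " x "),
              paste(x$voxel_spacing_um, collapse = "/")))
  cat(sprintf("  PSF sigma (z,y,x): %s um; snr %s; background %g; seed %d\n",
              paste(x$psf_sigma_um, collapse = "/"),
              format(x$snr), x$background_level, x$seed))
  invisible(x)
}

# Effective rendered sigma of a punctum / tube cross-section (PSF
# convolved with the object's own Gaussian size).
punctum_sigma <- function(config)
  sqrt(config$psf_sigma_um^2 + config$centriole_sigma_um^2)
tube_sigma <- function(config)
  sqrt(config$psf_sigma_um^2 + config$cilium_sigma_um^2)

# Peak signal amplitude implied by the configured SNR. With snr = Inf the
# render is noiseless and a fixed nominal amplitude is used.
peak_amplitude <- function(config) {
  nsd <- sqrt(config$background_level + config$read_sigma^2)
  if (is.infinite(config$snr)) return(if (nsd > 0) 10 * nsd else 100)
  config$snr * nsd
}

# --- low-level rendering -------------------------------------------------

# Render a set of anisotropic Gaussian blobs into a fresh 3D (z,y,x)
# array. Accumulation uses linear indexing into a locally owned array so
# thousands of kernels cost no array copies.
render_blobs <- function(dims, spacing_um, centers_um, sigma_um,
                         amplitudes, radius_sigmas = 3.5) {
  a <- array(0, dim = dims)
  centers_um <- rbind(centers_um)
  n <- nrow(centers_um)
  if (n == 0L) return(a)
  if (is.null(dim(sigma_um))) sigma_um <- matrix(sigma_um, n, 3, byrow = TRUE)
  amplitudes <- rep_len(amplitudes, n)
  d12 <- dims[1] * dims[2]
  for (i in seq_len(n)) {
    g <- vector("list", 3L); idx <- vector("list", 3L)
    ok <- TRUE
    for (ax in 1:3) {
      c_vox <- centers_um[i, ax] / spacing_um[ax]  # 0-based
      r <- ceiling(radius_sigmas * sigma_um[i, ax] / spacing_um[ax])
      lo <- max(0L, floor(c_vox - r)); hi <- min(dims[ax] - 1L,
                                                 ceiling(c_vox + r))
      if (hi < lo) { ok <- FALSE; break }
      ii <- lo:hi
      idx[[ax]] <- ii
      g[[ax]] <- exp(-((ii - c_vox) * spacing_um[ax])^2 /
                       (2 * sigma_um[i, ax]^2))
    }
    if (!ok) next
    blk <- amplitudes[i] * (g[[1]] %o% g[[2]] %o% g[[3]])
    lin <- outer(outer(idx[[1]] + 1L, idx[[2]] * dims[1], "+"),
                 idx[[3]] * d12, "+")
    a[lin] <- a[lin] + blk
  }
  a
}

# Kernel centers and amplitudes for a filament of Gaussian cross-section
# along a polyline, with amplitude normalized so the intensity plateau
# along the backbone equals `amplitude`. Returns a list suitable for
# pooling several filaments into one render_blobs() call.
tube_kernels <- function(polyline_um, sigma_um, amplitude, step_um = 0.08) {
  pts <- resample_polyline(polyline_um, step_um)
  n <- nrow(pts)
  if (n < 2L) return(list(centers = pts, amps = amplitude))
  tang <- rbind(pts[2, ] - pts[1, ],
                pts[seq(3, n), , drop = FALSE] -
                  pts[seq(1, n - 2), , drop = FALSE],
                pts[n, ] - pts[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  sig_t <- sqrt(colSums(t(tang^2) * sigma_um^2))
  list(centers = pts, amps = amplitude * step_um / (sqrt(2 * pi) * sig_t))
}

# Resample a polyline at (approximately) equal arc steps.
resample_polyline <- function(pts, step_um) {
  pts <- rbind(pts)
  L <- polyline_length(pts)
  if (L == 0) return(pts[1, , drop = FALSE])
  cl <- polyline_cumlen(pts)
  s <- seq(0, L, by = step_um)
  if (s[length(s)] < L) s <- c(s, L)
  out <- matrix(0, length(s), ncol(pts))
  for (j in seq_len(ncol(pts)))
    out[, j] <- stats::approx(cl, pts[, j], xout = s)$y
  out
}

# Apply the configured noise model: Poisson shot noise on signal plus
# background, plus Gaussian read noise. snr = Inf returns the noiseless
# render (signal + background).
apply_noise <- function(clean, config) {
  if (is.infinite(config$snr)) return(clean + config$background_level)
  lam <- pmax(clean + config$background_level, 0)
  n <- length(lam)
  img <- stats::rpois(n, lam) + stats::rnorm(n, 0, config$read_sigma)
  array(img, dim = dim(clean))
}

# Dart-throwing placement of n points on the apical dome shell of the
# knob with a minimum separation: docked centrioles sit just under the
# apical knob membrane, where the cilia emerge. `theta_max` is the polar
# angle from the apical direction bounding the dome. Errors if placement
# fails (region too crowded).
sample_shell_points <- function(n, center, radius, min_sep,
                                inner_frac = 0.7, theta_max = 105 * pi / 180,
                                aniso_sep = c(2.4, 1.15, 1.15),
                                max_tries = 60000L, max_restarts = 25L) {
  cos_min <- cos(theta_max)
  for (attempt in seq_len(max_restarts)) {
    pts <- matrix(0, 0, 3)
    tries <- 0L
    while (nrow(pts) < n && tries < max_tries) {
      tries <- tries + 1L
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      if (-u[1] < cos_min) next  # apical = decreasing z
      r <- radius * (stats::runif(1, inner_frac^3, 1))^(1 / 3)
      p <- center + r * u
      ok <- TRUE
      if (nrow(pts) > 0L) {
        dd <- sweep(pts, 2, p)
        # barrels dock side by side on the membrane: enforce both a
        # hard-core distance and an anisotropic (no vertical stacking)
        # separation
        ok <- min(sqrt(rowSums(dd^2))) >= min_sep &&
          min(sqrt(rowSums(sweep(dd, 2, aniso_sep, "/")^2))) >= 1
      }
      if (ok) pts <- rbind(pts, p)
    }
    if (nrow(pts) == n) return(unname(pts))
  }
  stop("cannot place centrioles: knob too crowded for min_separation_um",
       call. = FALSE)
}

# --- knob scenes ---------------------------------------------------------

#' Generate a dendritic-knob scene with centrioles and cilia
#'
#' Renders `n_centrioles` Gaussian puncta placed in a spherical knob
#' region (channel `"centrin"`) and `n_cilia` curved filaments of
#' configurable length anchored at distinct puncta (channel `"actub"`),
#' blurs nothing further (the PSF is part of the rendered sigma), and adds
#' Poisson shot noise plus Gaussian read noise. Ground truth records all
#' positions, curves and associations.
#'
#' @param config a [scene_config()].
#' @param n_centrioles number of centriole puncta.
#' @param n_cilia number of cilia; must not exceed `n_centrioles`.
#' @return list with elements `image` (a [voxel_grid()]) and `truth`
#'   (a `scene_truth`).
#' @export
generate_knob_scene <- function(config, n_centrioles, n_cilia = 0L) {
  stopifnot(inherits(config, "scene_config"))
  if (n_cilia > n_centrioles)
    stop("'n_cilia' must not exceed 'n_centrioles'", call. = FALSE)
  if (n_centrioles < 0L || n_cilia < 0L)
    stop("counts must be non-negative", call. = FALSE)
  d <- config$image_shape
  sp <- config$voxel_spacing_um
  ext <- (d - 1) * sp
  with_seed(config$seed, {
    clean_cen <- array(0, dim = d)
    clean_cil <- array(0, dim = d)
    spots <- matrix(numeric(0), 0, 3,
                    dimnames = list(NULL, c("z_um", "y_um", "x_um")))
    curves <- list()
    cil2spot <- integer(0)
    if (n_centrioles > 0L) {
      # knob near the basal face, leaving apical headroom for the cilia
      center <- c(ext[1] - config$knob_radius_um - 0.35,
                  ext[2] / 2, ext[3] / 2)
      pts <- sample_shell_points(n_centrioles, center,
                                 config$knob_radius_um,
                                 config$min_separation_um)
      colnames(pts) <- c("z_um", "y_um", "x_um")
      spots <- pts
      A <- peak_amplitude(config)
      clean_cen <- render_blobs(d, sp, pts, punctum_sigma(config), A)
      if (n_cilia > 0L) {
        anchors <- sample(n_centrioles, n_cilia)
        sig_t <- tube_sigma(config)
        kc <- list(); ka <- list()
        for (k in seq_len(n_cilia)) {
          base <- pts[anchors[k], ]
          L <- stats::runif(1, config$cilium_length_range_um[1],
                            config$cilium_length_range_um[2])
          curve <- sample_cilium_curve(base, center, L, config, ext)
          curves[[k]] <- curve
          cil2spot[k] <- anchors[k]
          tk <- tube_kernels(curve, sig_t, A)
          kc[[k]] <- tk$centers; ka[[k]] <- tk$amps
        }
        clean_cil <- render_blobs(d, sp, do.call(rbind, kc), sig_t,
                                  unlist(ka))
      }
    }
    img <- array(0, dim = c(1L, 2L, d))
    img[1, 1, , , ] <- apply_noise(clean_cen, config)
    img[1, 2, , , ] <- apply_noise(clean_cil, config)
    grid <- voxel_grid(img, spacing_um = sp,
                       channel_names = c("centrin", "actub"))
    truth <- scene_truth(
      spot_positions_um = spots,
      group_membership = rep(0L, nrow(spots)),
      cilium_curves = curves,
      cilium_to_spot = cil2spot)
    list(image = grid, truth = truth)
  })
}

# Sample one cilium backbone. Cilia emerge along the local surface
# normal of the apical knob dome (with an apical bias) and bend into a
# rising, gently curling fan above the knob, the way olfactory cilia
# spread from the dendritic knob. Rays from neighbouring docked
# centrioles diverge, which keeps filaments resolvable under the
# anisotropic PSF. The tangent field is integrated at a fixed arc step so
# the arc length equals the drawn length; curves leaving the image bounds
# are redrawn with smaller jitter and, as a last resort, shortened.
sample_cilium_curve <- function(base, knob_center, length_um, config, ext,
                                margin = 0.4, step_um = 0.25) {
  apical <- c(-1, 0, 0)  # decreasing z
  unit <- function(v) v / max(sqrt(sum(v^2)), 1e-9)
  n0 <- unit(base - knob_center)
  L <- length_um
  bend <- config$cilium_bend_frac
  r_cap <- min(ext[2], ext[3]) / 2 - 1.2  # lateral steering radius
  for (try in seq_len(200L)) {
    jit <- max(0.02, 0.1 * (1 - try / 100))
    dir0 <- unit(n0 + 0.9 * apical + stats::rnorm(3, 0, jit))
    p <- base
    pts <- matrix(p, 1, 3)
    s <- 0
    while (s < L - 1e-9) {
      tg <- dir0
      rad <- c(0, p[2] - knob_center[2], p[3] - knob_center[3])
      rn <- sqrt(sum(rad^2))
      # steer upward near the lateral wall, outward near the apical face
      wlat <- min(1, max(0, (rn / r_cap - 0.72) / 0.2))
      if (wlat > 0) tg <- unit((1 - wlat) * tg + wlat * apical)
      wtop <- min(1, max(0, (3.6 - p[1]) / 2.6))
      if (wtop > 0) {
        outw <- if (rn > 1e-6) rad / rn else c(0, 1, 0)
        tg <- unit((1 - wtop) * tg + wtop * outw)
      }
      # gentle in-plane waviness so filaments are curved, not straight
      u <- sin(bend * s * 2 * pi / max(L, 1))
      perp <- unit(c(0, -dir0[3], dir0[2]))
      tg <- unit(tg + 0.15 * u * perp)
      h <- min(step_um, L - s)
      p <- p + tg * h
      s <- s + h
      pts <- rbind(pts, p)
    }
    inside <- all(pts >= margin) && all(sweep(pts, 2, ext - margin) <= 0)
    if (inside) {
      colnames(pts) <- c("z_um", "y_um", "x_um")
      return(pts)
    }
    if (try %% 50 == 0) L <- max(config$cilium_length_range_um[1], L * 0.8)
  }
  stop("could not fit a cilium inside the image bounds", call. = FALSE)
}

# Ground-truth container shared by all generators.
scene_truth <- function(spot_positions_um = NULL, group_membership = NULL,
                        cilium_curves = NULL, cilium_to_spot = NULL,
                        track_centroids_um = NULL,
                        track_velocities_um_per_min = NULL,
                        fiducial_index = NULL, frame_times_min = NULL,
                        compartment_labels = NULL, count_table = NULL) {
  structure(list(
    spot_positions_um = spot_positions_um,
    group_membership = group_membership,
    cilium_curves = cilium_curves,
    cilium_to_spot = cilium_to_spot,
    track_centroids_um = track_centroids_um,
    track_velocities_um_per_min = track_velocities_um_per_min,
    fiducial_index = fiducial_index,
    frame_times_min = frame_times_min,
    compartment_labels = compartment_labels,
    count_table = count_table), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat("<scene_truth>\n")
  if (!is.null(x$spot_positions_um))
    cat(sprintf("  %d spots, %d cilia\n", nrow(x$spot_positions_um),
                length(x$cilium_curves)))
  if (!is.null(x$track_centroids_um))
    cat(sprintf("  %d tracked groups over %d frames (fiducial #%d)\n",
                dim(x$track_centroids_um)[2], dim(x$track_centroids_um)[1],
                x$fiducial_index))
  if (!is.null(x$count_table))
    cat(sprintf("  count table: %d records\n", nrow(x$count_table)))
  invisible(x)
}

# --- time-lapses ---------------------------------------------------------

#' Generate a 4D time-lapse of migrating centriole groups
#'
#' Each group is a tight cluster of 3-12 puncta whose centroid moves at
#' its assigned velocity along the apical axis (apical positive) with
#' i.i.d. per-frame positional jitter. A static fiducial cluster is always
#' included as the last group. Ground truth records the per-frame rendered
#' centroids.
#'
#' @param config a [scene_config()].
#' @param n_groups number of moving groups.
#' @param velocities_um_per_min signed apical velocities, one per group.
#' @param n_frames number of frames (>= 2).
#' @param frame_interval_min minutes between frames.
#' @param positional_noise_um standard deviation of per-frame group jitter.
#' @param drift_um_per_min optional common (z,y,x) stage drift applied to
#'   every object including the fiducial.
#' @param max_velocity_um_per_min sanity bound on |velocity|.
#' @return list with `movie` (a [voxel_grid()] with `n_frames` timepoints)
#'   and `truth` (a `scene_truth` with `track_centroids_um` of dimension
#'   frames x groups+1 x 3).
#' @export
generate_timelapse <- function(config, n_groups, velocities_um_per_min,
                               n_frames, frame_interval_min = 10,
                               positional_noise_um = 0.05,
                               drift_um_per_min = c(0, 0, 0),
                               max_velocity_um_per_min = 1) {
  stopifnot(inherits(config, "scene_config"))
  if (length(velocities_um_per_min) != n_groups)
    stop("length(velocities_um_per_min) must equal 'n_groups'",
         call. = FALSE)
  if (n_frames < 2L) stop("'n_frames' must be >= 2", call. = FALSE)
  if (any(abs(velocities_um_per_min) > max_velocity_um_per_min))
    stop(sprintf("velocities exceed the sanity bound %g um/min",
                 max_velocity_um_per_min), call. = FALSE)
  d <- config$image_shape
  sp <- config$voxel_spacing_um
  ext <- (d - 1) * sp
  times <- (seq_len(n_frames) - 1L) * frame_interval_min
  with_seed(config$seed, {
    ntot <- n_groups + 1L  # moving groups + static fiducial
    vels <- c(velocities_um_per_min, 0)
    sizes <- sample(3:12, ntot, replace = TRUE)
    # members as offsets about the group centroid
    offsets <- lapply(sizes, function(k)
      cbind(stats::rnorm(k, 0, 0.4), stats::rnorm(k, 0, 0.4),
            stats::rnorm(k, 0, 0.4)))
    # starting centroids: spread laterally; start z placed so the whole
    # trajectory stays inside the volume (apical = decreasing z)
    lat <- seq(0.2, 0.8, length.out = ntot) * ext[3]
    starts <- matrix(0, ntot, 3)
    for (g in seq_len(ntot)) {
      dz_total <- -vels[g] * times[n_frames]
      zlo <- 2 + max(0, -dz_total)
      zhi <- ext[1] - 2 - max(0, dz_total)
      if (zlo > zhi)
        warning(sprintf(
          paste0("group %d travels %.1f um but the z extent is %.1f um; ",
                 "it will leave the rendered volume"),
          g, abs(vels[g]) * times[n_frames], ext[1]), call. = FALSE)
      starts[g, ] <- c(stats::runif(1, min(zlo, zhi), max(zlo, zhi)),
                       ext[2] / 2 + stats::rnorm(1, 0, 1), lat[g])
    }
    cent <- array(0, dim = c(n_frames, ntot, 3))
    for (f in seq_len(n_frames)) for (g in seq_len(ntot)) {
      jit <- if (positional_noise_um > 0)
        stats::rnorm(3, 0, positional_noise_um) else c(0, 0, 0)
      cent[f, g, ] <- starts[g, ] +
        c(-vels[g] * times[f], 0, 0) +
        drift_um_per_min * times[f] + jit
    }
    A <- peak_amplitude(config)
    sig <- punctum_sigma(config)
    img <- array(0, dim = c(n_frames, 1L, d))
    for (f in seq_len(n_frames)) {
      mem <- do.call(rbind, lapply(seq_len(ntot), function(g)
        sweep(offsets[[g]], 2, cent[f, g, ], "+")))
      clean <- render_blobs(d, sp, mem, sig, A)
      img[f, 1, , , ] <- apply_noise(clean, config)
    }
    movie <- voxel_grid(img, spacing_um = sp, channel_names = "centrin")
    truth <- scene_truth(
      track_centroids_um = cent,
      track_velocities_um_per_min = velocities_um_per_min,
      fiducial_index = ntot,
      frame_times_min = times)
    list(movie = movie, truth = truth)
  })
}

# --- count tables --------------------------------------------------------

#' Generate a paired drug/control table of centriole-group counts
#'
#' For each animal x timepoint x compartment, emits a paired (control,
#' drug) pair of records. Counts are Poisson with mean
#' `density x length/100 x multiplier` (multiplier 1 for the control arm);
#' each record draws its own scored basal-lamina length uniformly from
#' `length_um_range`, mirroring the per-explant lengths of a real scoring
#' session.
#'
#' @param n_animals number of animals (paired halves per animal).
#' @param timepoints character vector of timepoint labels.
#' @param compartments character vector of compartment labels.
#' @param base_density_per_100um expected groups per 100 um of basal
#'   lamina in the control arm; scalar or named by compartment.
#' @param drug_multiplier_by_compartment named numeric (by compartment) or
#'   named list of named numerics (compartment, then timepoint) giving the
#'   drug-arm fold enrichment.
#' @param length_um_range interval from which scored lengths are drawn.
#' @param seed RNG seed.
#' @return a data.frame of class `group_count_table` with columns
#'   animal_id, condition, timepoint, compartment, count, basal_length_um,
#'   normalized_per_100um.
#' @export
generate_count_table <- function(n_animals = 2L,
                                 timepoints = c("1h", "6h"),
                                 compartments = c("subapical",
                                                  "middle_basal"),
                                 base_density_per_100um = 2.9,
                                 drug_multiplier_by_compartment = NULL,
                                 length_um_range = c(900, 1150),
                                 seed = 1L) {
  if (length(timepoints) == 0L || length(compartments) == 0L)
    stop("'timepoints' and 'compartments' must be non-empty", call. = FALSE)
  if (n_animals < 1L) stop("'n_animals' must be >= 1", call. = FALSE)
  assert_positive(base_density_per_100um, "base_density_per_100um")
  assert_positive(length_um_range, "length_um_range")
  dens_for <- function(comp) {
    if (!is.null(names(base_density_per_100um)) &&
        comp %in% names(base_density_per_100um))
      base_density_per_100um[[comp]]
    else unname(base_density_per_100um[1])
  }
  mult_for <- function(comp, tp) {
    m <- drug_multiplier_by_compartment
    if (is.null(m)) return(1)
    v <- if (comp %in% names(m)) m[[comp]] else 1
    if (length(v) > 1L || !is.null(names(v)))
      v <- if (tp %in% names(v)) v[[tp]] else 1
    v <- as.numeric(v)
    if (v <= 0) stop("drug multipliers must be positive", call. = FALSE)
    v
  }
  with_seed(seed, {
    rows <- list()
    for (a in seq_len(n_animals)) for (tp in timepoints)
      for (comp in compartments) for (cond in c("control", "drug")) {
        len <- stats::runif(1, length_um_range[1], length_um_range[2])
        mu <- dens_for(comp) * len / 100 *
          (if (cond == "drug") mult_for(comp, tp) else 1)
        cnt <- stats::rpois(1, mu)
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = sprintf("A%d", a), condition = cond, timepoint = tp,
          compartment = comp, count = cnt, basal_length_um = len,
          normalized_per_100um = 100 * cnt / len,
          stringsAsFactors = FALSE)
      }
    out <- do.call(rbind, rows)
    class(out) <- c("group_count_table", "data.frame")
    out
  })
}
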