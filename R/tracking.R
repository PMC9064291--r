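# Tracking: side-view projection, frame-to-frame linking of centriole
# groups with fiducial drift correction, net migration rates and direction
# classes, and kymograph construction.

#' Maximum-intensity side-view projection
#'
#' Projects a movie (or single stack) along one lateral axis per frame and
#' channel, producing a side view in which the apical axis is preserved.
#' Projecting along the apical axis is refused, since it would destroy the
#' coordinate being measured.
#'
#' @param movie a [voxel_grid()].
#' @param axis `"y"` or `"x"`: the lateral axis to project away.
#' @return a [voxel_grid()] with a singleton extent on the projected axis.
#' @export
project_side_view <- function(movie, axis = "x") {
  stopifnot(inherits(movie, "voxel_grid"))
  if (axis == movie$apical_axis$axis)
    stop("refusing to project along the apical axis", call. = FALSE)
  ai <- match(axis, c("z", "y", "x"))
  if (is.na(ai)) stop("'axis' must be one of z, y, x", call. = FALSE)
  d <- dim(movie$data)
  nd <- d; nd[2 + ai] <- 1L
  out <- array(0, dim = nd)
  for (t in seq_len(d[1])) for (c in seq_len(d[2])) {
    a <- movie$data[t, c, , , ]
    dim(a) <- d[3:5]
    out[t, c, , , ] <- apply(a, setdiff(1:3, ai), max)
  }
  voxel_grid(out, spacing_um = movie$spacing_um,
             channel_names = movie$channel_names,
             apical_axis = movie$apical_axis)
}

#' Link centriole groups across frames into tracks
#'
#' Greedy nearest-neighbour linking: at each frame transition the closest
#' (track head, new group) pair within `gating_radius_um` is linked first,
#' then the next closest, and so on; unlinked groups start new tracks, and
#' track heads missing for up to `max_gap` frames remain eligible. If a
#' fiducial track is identified, its per-frame position is interpolated
#' and subtracted from all positions before displacement and rate
#' computation, cancelling common drift. The net rate follows the
#' first/last-observation convention: (last - first corrected apical
#' position) / elapsed time; a least-squares regression rate over all
#' observed frames is reported alongside.
#'
#' @param per_frame_groups list (one element per frame) of data.frames
#'   with columns centroid_z_um, centroid_y_um, centroid_x_um (e.g. the
#'   `groups` element of [cluster_groups()]).
#' @param frame_times_min numeric vector of frame times in minutes.
#' @param gating_radius_um maximum link distance between frames.
#' @param max_gap frames a track may skip and still be extended.
#' @param fiducial_id track id (see return) of the static fiducial, or
#'   `NA` to skip drift correction.
#' @param apical_axis apical convention (as in [voxel_grid()]).
#' @param displacement_threshold_um threshold for direction classes.
#' @return a data.frame of class `track_table`: track_id, n_frames,
#'   first_frame, last_frame, elapsed_min, net_displacement_um,
#'   rate_um_per_min, regression_rate_um_per_min, direction; per-frame
#'   corrected apical positions in `attr(, "positions")`.
#' @export
link_tracks <- function(per_frame_groups, frame_times_min,
                        gating_radius_um = 3, max_gap = 2L,
                        fiducial_id = NA,
                        apical_axis = list(axis = "z", sign = -1),
                        displacement_threshold_um = 0.5) {
  nf <- length(per_frame_groups)
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  if (length(frame_times_min) != nf)
    stop("'frame_times_min' must match the number of frames", call. = FALSE)
  if (gating_radius_um <= 0)
    stop("'gating_radius_um' must be positive", call. = FALSE)
  getpos <- function(df) {
    m <- as.matrix(df[, c("centroid_z_um", "centroid_y_um",
                          "centroid_x_um"), drop = FALSE])
    unname(m)
  }
  # tracks: list of list(frames = int vec, pos = matrix)
  tracks <- list()
  active <- integer(0)  # indices into tracks
  p0 <- getpos(per_frame_groups[[1]])
  for (i in seq_len(nrow(p0))) {
    tracks[[i]] <- list(frames = 1L, pos = p0[i, , drop = FALSE])
    active <- c(active, i)
  }
  for (f in 2:nf) {
    pnew <- getpos(per_frame_groups[[f]])
    nnew <- nrow(pnew)
    # drop stale heads
    if (length(active) > 0L) {
      last_seen <- vapply(tracks[active], function(tr)
        tr$frames[length(tr$frames)], integer(1))
      active <- active[f - last_seen <= max_gap + 1L]
    }
    if (nnew > 0L && length(active) > 0L) {
      heads <- t(vapply(tracks[active], function(tr)
        tr$pos[nrow(tr$pos), ], numeric(3)))
      dmat <- matrix(Inf, length(active), nnew)
      for (j in seq_len(nnew))
        dmat[, j] <- sqrt(rowSums(sweep(heads, 2, pnew[j, ])^2))
      linked_new <- logical(nnew)
      repeat {
        m <- which.min(dmat)
        if (length(m) == 0L || !is.finite(dmat[m])) break
        if (dmat[m] > gating_radius_um) break
        ti <- (m - 1) %% nrow(dmat) + 1
        gj <- (m - 1) %/% nrow(dmat) + 1
        tr <- tracks[[active[ti]]]
        tr$frames <- c(tr$frames, f)
        tr$pos <- rbind(tr$pos, pnew[gj, ])
        tracks[[active[ti]]] <- tr
        linked_new[gj] <- TRUE
        dmat[ti, ] <- Inf; dmat[, gj] <- Inf
      }
    } else linked_new <- rep(FALSE, nnew)
    for (j in which(!linked_new)) {
      tracks[[length(tracks) + 1L]] <-
        list(frames = f, pos = pnew[j, , drop = FALSE])
      active <- c(active, length(tracks))
    }
  }
  ax <- match(apical_axis$axis, c("z", "y", "x"))
  # fiducial correction: interpolate the fiducial position over frames
  corr <- matrix(0, nf, 3)
  if (!is.na(fiducial_id)) {
    if (fiducial_id < 1L || fiducial_id > length(tracks))
      stop("fiducial track id not found", call. = FALSE)
    fid <- tracks[[fiducial_id]]
    if (length(fid$frames) < nf / 2)
      stop("fiducial absent in more than half the frames", call. = FALSE)
    for (k in 1:3)
      corr[, k] <- stats::approx(fid$frames, fid$pos[, k],
                                 xout = seq_len(nf), rule = 2)$y
  }
  rows <- list(); positions <- list()
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    cpos <- tr$pos - corr[tr$frames, , drop = FALSE]
    apic <- apical_axis$sign * cpos[, ax]
    tt <- frame_times_min[tr$frames]
    nfr <- length(tr$frames)
    if (nfr >= 2L) {
      elapsed <- tt[nfr] - tt[1]
      net <- apic[nfr] - apic[1]
      rate <- net / elapsed
      reg <- unname(stats::coef(stats::lm(apic ~ tt))[2])
    } else { elapsed <- 0; net <- 0; rate <- NA_real_; reg <- NA_real_ }
    rows[[i]] <- data.frame(
      track_id = i, n_frames = nfr, first_frame = tr$frames[1],
      last_frame = tr$frames[nfr], elapsed_min = elapsed,
      net_displacement_um = net, rate_um_per_min = rate,
      regression_rate_um_per_min = reg,
      direction = classify_direction_value(net, displacement_threshold_um))
    positions[[i]] <- data.frame(frame = tr$frames, time_min = tt,
                                 apical_um = apic)
  }
  out <- do.call(rbind, rows)
  attr(out, "positions") <- positions
  class(out) <- c("track_table", "data.frame")
  out
}

classify_direction_value <- function(net_displacement_um, threshold_um) {
  if (is.na(net_displacement_um)) return(NA_character_)
  if (net_displacement_um > threshold_um) "apical"
  else if (net_displacement_um < -threshold_um) "basal"
  else "none"
}

#' Classify a track's net direction of movement
#'
#' Apical if the net displacement exceeds `+displacement_threshold_um`,
#' basal if below the negative threshold, otherwise `"none"`.
#'
#' @param track one row of a `track_table` (or a list with
#'   `net_displacement_um`).
#' @param displacement_threshold_um no-movement threshold, micrometres.
#' @return `"apical"`, `"basal"` or `"none"`.
#' @export
classify_direction <- function(track, displacement_threshold_um = 0.5) {
  classify_direction_value(track$net_displacement_um,
                           displacement_threshold_um)
}

#' Build a kymograph along a sampling line
#'
#' For each frame the side-view projection (along the movie's x axis) is
#' sampled by bilinear interpolation along the polyline, averaged over
#' `width_um` perpendicular to it, and the resulting profiles are stacked
#' in time order (rows = frames, columns = arc position).
#'
#' @param movie a [voxel_grid()].
#' @param line_um polyline matrix with columns (z_um, y_um) in the
#'   side-view plane.
#' @param width_um perpendicular averaging width.
#' @param channel channel name or index.
#' @param pixel_size_um arc sampling step; defaults to the finest spacing.
#' @return an object of class `kymograph` with fields `data` (time x arc
#'   position), `line_um`, `width_um`, `pixel_size_um`, `times`.
#' @export
build_kymograph <- function(movie, line_um, width_um = 1,
                            channel = 1L, pixel_size_um = NULL) {
  stopifnot(inherits(movie, "voxel_grid"))
  d <- dim(movie$data)
  sp <- movie$spacing_um
  line_um <- as.matrix(line_um)
  if (is.null(pixel_size_um)) pixel_size_um <- min(sp)
  ext <- (d[3:4] - 1) * sp[1:2]
  if (any(line_um < 0) || any(line_um[, 1] > ext[1]) ||
      any(line_um[, 2] > ext[2]))
    stop("sampling line exits the image bounds", call. = FALSE)
  pts <- resample_polyline(line_um, pixel_size_um)
  n <- nrow(pts)
  # unit tangents and perpendiculars in the (z, y) plane
  tang <- rbind(pts[2, ] - pts[1, ],
                pts[seq(3, n), , drop = FALSE] -
                  pts[seq(1, n - 2), , drop = FALSE],
                pts[n, ] - pts[n - 1, ])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  perp <- cbind(-tang[, 2], tang[, 1])
  offs <- seq(-width_um / 2, width_um / 2, by = pixel_size_um)
  if (length(offs) == 0L) offs <- 0
  proj <- project_side_view(movie, axis = "x")
  km <- matrix(0, d[1], n)
  for (t in seq_len(d[1])) {
    pl <- proj$data[t, if (is.character(channel))
      match(channel, movie$channel_names) else channel, , , 1]
    dim(pl) <- d[3:4]
    acc <- 0
    for (o in offs) {
      q <- pts + o * perp
      acc <- acc + interp2(pl, q, sp[1:2])
    }
    km[t, ] <- acc / length(offs)
  }
  structure(list(data = km, line_um = line_um, width_um = width_um,
                 pixel_size_um = pixel_size_um,
                 arc_um = polyline_cumlen(pts)[seq_len(n)],
                 times = seq_len(d[1])),
            class = "kymograph")
}

# Bilinear interpolation of a 2D plane at physical positions (rows z,y).
interp2 <- function(pl, pts_um, sp) {
  d <- dim(pl)
  p <- sweep(rbind(pts_um), 2, sp, "/")
  p[, 1] <- pmin(pmax(p[, 1], 0), d[1] - 1)
  p[, 2] <- pmin(pmax(p[, 2], 0), d[2] - 1)
  f <- floor(p); r <- p - f; i0 <- f + 1
  val <- 0
  for (bz in 0:1) for (by in 0:1) {
    wz <- if (bz == 0) 1 - r[, 1] else r[, 1]
    wy <- if (by == 0) 1 - r[, 2] else r[, 2]
    iz <- pmin(i0[, 1] + bz, d[1]); iy <- pmin(i0[, 2] + by, d[2])
    val <- val + wz * wy * pl[cbind(iz, iy)]
  }
  val
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> %d frames x %d arc samples (step %.3f um, width %g um)\n",
              nrow(x$data), ncol(x$data), x$pixel_size_um, x$width_um))
  invisible(x)
}

#' @export
plot.kymograph <- function(x, ...) {
  graphics::image(x = x$arc_um, y = x$times, z = t(x$data),
                  xlab = "arc position (um)", ylab = "frame",
                  col = grDevices::hcl.colors(64, "inferno"), ...)
  invisible(x)
}

#' Estimate the ridge slope of a kymograph
#'
#' Finds the intensity maximum of each row and regresses its arc position
#' on time, returning the slope in micrometres per frame-time unit.
#'
#' @param kymo a `kymograph`.
#' @param times_min optional frame times; defaults to frame index.
#' @return slope of the fitted ridge (um per time unit).
#' @export
kymograph_ridge_slope <- function(kymo, times_min = NULL) {
  pos <- kymo$arc_um[apply(kymo$data, 1, which.max)]
  tt <- if (is.null(times_min)) kymo$times else times_min
  unname(stats::coef(stats::lm(pos ~ tt))[2])
}
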