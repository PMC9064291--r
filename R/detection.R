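# Detection: centrioles as 3D puncta via a multi-scale Laplacian-of-
# Gaussian blob detector, cilia as filaments via Hessian tubeness,
# thresholding and geodesic path tracing, and the one-to-one centriole-
# cilium association computed as an optimal assignment.

#' Detect centriole puncta in a 3D channel
#'
#' Multi-scale Laplacian-of-Gaussian blob detection. For each scale the
#' channel is smoothed with an anisotropic Gaussian (axial sigma =
#' `axial_ratio` times lateral), the scale-normalized negative Laplacian
#' is computed, and 26-neighbourhood maxima above threshold are collected.
#' Candidates are refined to subvoxel positions by local intensity-weighted
#' centroids and de-duplicated so that no two retained spots lie within
#' 0.7 times their combined scale (anisotropy-normalized distance).
#' Spots are returned sorted by descending response.
#'
#' @param grid a [voxel_grid()].
#' @param channel channel name or index.
#' @param scale_range_um lateral blob-scale interval bracketing the
#'   expected centriole radius (expanded scale).
#' @param n_scales number of geometrically spaced scales.
#' @param threshold_policy `"otsu"` (Otsu on the positive response, floored
#'   at `noise_k` robust noise SDs) or `"absolute"`.
#' @param threshold_abs absolute response threshold for policy "absolute".
#' @param noise_k noise floor multiplier for policy "otsu".
#' @param axial_ratio axial-to-lateral sigma ratio of the detector.
#' @param t timepoint index.
#' @param review optional review table (or CSV path) with columns `id` and
#'   `keep`; detections with `keep` false are dropped, making a manual
#'   inspection pass reproducible.
#' @return a data.frame of class `spot_table` with columns id, z_um, y_um,
#'   x_um, scale_um, intensity, roi_id.
#' @export
detect_spots <- function(grid, channel = "centrin",
                         scale_range_um = c(0.25, 0.5), n_scales = 3L,
                         threshold_policy = c("otsu", "absolute"),
                         threshold_abs = NULL, noise_k = 6,
                         axial_ratio = 1.5, t = 1L, review = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  threshold_policy <- match.arg(threshold_policy)
  vol <- grid_channel(grid, channel, t)
  sp <- grid$spacing_um
  d <- dim(vol)
  empty <- data.frame(id = integer(0), z_um = numeric(0), y_um = numeric(0),
                      x_um = numeric(0), scale_um = numeric(0),
                      intensity = numeric(0), roi_id = NA_integer_[0])
  class(empty) <- c("spot_table", "data.frame")
  if (all(vol == vol[1])) return(empty)
  scales <- exp(seq(log(scale_range_um[1]), log(scale_range_um[2]),
                    length.out = n_scales))
  cand <- list()
  for (s in scales) {
    sig_um <- c(s * axial_ratio, s, s)
    sm <- gauss_smooth3(vol, sig_um / sp)
    R <- -(sig_um[1]^2 * second_diff3(sm, 1L, sp[1]) +
           sig_um[2]^2 * second_diff3(sm, 2L, sp[2]) +
           sig_um[3]^2 * second_diff3(sm, 3L, sp[3]))
    thr <- if (threshold_policy == "absolute") {
      if (is.null(threshold_abs))
        stop("'threshold_abs' required for policy \"absolute\"",
             call. = FALSE)
      threshold_abs
    } else {
      pos <- R[R > 0]
      if (length(pos) < 2L) next
      max(otsu_threshold(pos), noise_k * noise_sigma(as.vector(R)))
    }
    bm <- box_max3(R)
    hit <- which(R >= bm & R > thr, arr.ind = TRUE)
    if (nrow(hit) == 0L) next
    # edge replication inflates the response at the faces; ignore a
    # one-sigma border
    m <- ceiling(sig_um / sp) + 1L
    inb <- hit[, 1] > m[1] & hit[, 1] <= d[1] - m[1] &
      hit[, 2] > m[2] & hit[, 2] <= d[2] - m[2] &
      hit[, 3] > m[3] & hit[, 3] <= d[3] - m[3]
    hit <- hit[inb, , drop = FALSE]
    if (nrow(hit) == 0L) next
    pos <- refine_subvoxel(R, hit, sig_um / sp, sp)
    cand[[length(cand) + 1L]] <- data.frame(
      z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
      scale_um = s, intensity = R[hit])
  }
  if (length(cand) == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$intensity), , drop = FALSE]
  # greedy de-duplication across scales
  keep <- logical(nrow(cand))
  kz <- ky <- kx <- ks <- numeric(0)
  for (i in seq_len(nrow(cand))) {
    if (length(kz) > 0L) {
      dd <- sqrt(((cand$z_um[i] - kz) / axial_ratio)^2 +
                 (cand$y_um[i] - ky)^2 + (cand$x_um[i] - kx)^2)
      if (any(dd < 0.7 * (cand$scale_um[i] + ks))) next
    }
    keep[i] <- TRUE
    kz <- c(kz, cand$z_um[i]); ky <- c(ky, cand$y_um[i])
    kx <- c(kx, cand$x_um[i]); ks <- c(ks, cand$scale_um[i])
  }
  out <- cand[keep, , drop = FALSE]
  out <- data.frame(id = seq_len(nrow(out)), out, roi_id = NA_integer_)
  rownames(out) <- NULL
  if (!is.null(review)) {
    if (is.character(review)) review <- utils::read.csv(review)
    if (!all(c("id", "keep") %in% names(review)))
      stop("review table must have columns 'id' and 'keep'", call. = FALSE)
    drop_ids <- review$id[!as.logical(review$keep)]
    out <- out[!out$id %in% drop_ids, , drop = FALSE]
  }
  class(out) <- c("spot_table", "data.frame")
  out
}

# 3x3x3 box maximum via three per-axis running maxima.
box_max3 <- function(a) {
  for (axis in 1:3) {
    n <- dim(a)[axis]
    up <- pmin(seq_len(n) + 1L, n)
    dn <- pmax(seq_len(n) - 1L, 1L)
    a <- switch(axis,
                pmax(a[up, , , drop = FALSE], a, a[dn, , , drop = FALSE]),
                pmax(a[, up, , drop = FALSE], a, a[, dn, , drop = FALSE]),
                pmax(a[, , up, drop = FALSE], a, a[, , dn, drop = FALSE]))
  }
  a
}

# Subvoxel refinement: response-weighted centroid in a window of about one
# sigma around each candidate voxel. Returns physical (z,y,x) positions.
refine_subvoxel <- function(R, hit, sigma_vox, spacing_um) {
  d <- dim(R)
  w <- pmax(1L, ceiling(sigma_vox))
  out <- matrix(0, nrow(hit), 3)
  for (k in seq_len(nrow(hit))) {
    i0 <- hit[k, ]
    zi <- max(1L, i0[1] - w[1]):min(d[1], i0[1] + w[1])
    yi <- max(1L, i0[2] - w[2]):min(d[2], i0[2] + w[2])
    xi <- max(1L, i0[3] - w[3]):min(d[3], i0[3] + w[3])
    blk <- R[zi, yi, xi, drop = FALSE]
    wts <- pmax(blk - min(blk), 0)
    tot <- sum(wts)
    if (tot <= 0) { out[k, ] <- (i0 - 1) * spacing_um; next }
    gz <- apply(wts, 1, sum); gy <- apply(wts, 2, sum)
    gx <- apply(wts, 3, sum)
    out[k, ] <- c(sum((zi - 1) * gz) / tot * spacing_um[1],
                  sum((yi - 1) * gy) / tot * spacing_um[2],
                  sum((xi - 1) * gx) / tot * spacing_um[3])
  }
  out
}

#' Count centrioles, optionally per region of interest
#'
#' @param spots a `spot_table` from [detect_spots()].
#' @param roi optional integer label array (same grid as the image,
#'   0 = outside all regions).
#' @param spacing_um voxel spacing of `roi`, needed to map spot positions
#'   to voxels.
#' @return a list with `total`, and when `roi` is given a data.frame
#'   `per_roi` (roi_id, n) plus `outside` (spots in no region).
#' @export
count_centrioles <- function(spots, roi = NULL,
                             spacing_um = c(0.27, 0.11, 0.11)) {
  if (is.null(roi)) return(list(total = nrow(spots)))
  d <- dim(roi)
  vox <- cbind(pmin(pmax(round(spots$z_um / spacing_um[1]) + 1, 1), d[1]),
               pmin(pmax(round(spots$y_um / spacing_um[2]) + 1, 1), d[2]),
               pmin(pmax(round(spots$x_um / spacing_um[3]) + 1, 1), d[3]))
  lab <- roi[vox]
  ids <- sort(unique(lab[lab > 0]))
  per <- data.frame(roi_id = ids,
                    n = vapply(ids, function(i) sum(lab == i), integer(1)))
  list(total = nrow(spots), per_roi = per, outside = sum(lab == 0))
}

#' Detect cilia as filaments in a 3D channel
#'
#' The channel is smoothed, thresholded (half way between background and
#' bright signal), and restricted to voxels whose Hessian eigenvalues are
#' tube-like (two strongly negative, one near zero). 26-connected
#' components are traced by a geodesic double sweep (the path between the
#' two mutually farthest voxels), smoothed, and trimmed or extended to the
#' half-maximum intensity crossing at each end. Paths shorter than
#' `min_length_um` are discarded. Each cilium's base is the endpoint
#' nearer the spot channel's intensity-weighted centroid cloud.
#'
#' @param grid a [voxel_grid()].
#' @param channel cilium channel name or index.
#' @param min_length_um minimum accepted arc length.
#' @param smooth_sigma_um pre-smoothing sigma (z, y, x).
#' @param spot_channel channel used to orient bases; if absent, the image
#'   centroid of the cilium channel itself is used.
#' @param min_voxels components smaller than this are ignored as specks.
#' @param gate_frac tubeness strictness: a voxel survives only if its
#'   second-smallest Hessian eigenvalue is below `gate_frac` times the
#'   smallest (both strongly negative across the filament).
#' @param split_junctions recursively re-trace residual voxels so
#'   filaments joined at junctions are recovered as separate paths.
#' @param t timepoint index.
#' @return a data.frame of class `cilium_table` with columns id,
#'   length_um, base/tip coordinates, and the traced polylines (in um) in
#'   `attr(, "polylines")`.
#' @export
detect_cilia <- function(grid, channel = "actub", min_length_um = 2,
                         smooth_sigma_um = c(0.3, 0.15, 0.15),
                         spot_channel = "centrin", min_voxels = 30L,
                         gate_frac = 0.4, split_junctions = TRUE,
                         t = 1L) {
  stopifnot(inherits(grid, "voxel_grid"))
  vol <- grid_channel(grid, channel, t)
  sp <- grid$spacing_um
  d <- dim(vol)
  sm <- gauss_smooth3(vol, smooth_sigma_um / sp)
  base_lvl <- stats::median(sm)
  hi <- stats::quantile(sm, 0.999, names = FALSE)
  empty <- data.frame(id = integer(0), length_um = numeric(0),
                      base_z_um = numeric(0), base_y_um = numeric(0),
                      base_x_um = numeric(0), tip_z_um = numeric(0),
                      tip_y_um = numeric(0), tip_x_um = numeric(0))
  attr(empty, "polylines") <- list()
  class(empty) <- c("cilium_table", "data.frame")
  if (hi <= base_lvl) return(empty)
  thr <- base_lvl + 0.5 * (hi - base_lvl)
  vox <- which(sm > thr, arr.ind = TRUE)
  if (nrow(vox) == 0L) return(empty)
  # tubeness gate: the two cross-sectional curvatures must both be
  # strongly negative. This also severs blur "bridges" between nearby
  # filaments, whose midline is a saddle (lambda2 near zero).
  ev <- hessian_eigen_sparse(sm, vox, sp)
  tube <- ev[, 1] < 0 & ev[, 2] < gate_frac * ev[, 1]
  vox <- vox[tube, , drop = FALSE]
  if (nrow(vox) == 0L) return(empty)
  # plain 26-connectivity: a wider reach would re-bridge the gaps the
  # tubeness gate cuts between nearby parallel filaments
  shifts <- neighbor_shifts(1L, 1L, 1L)
  lab <- components_26(vox, d, shifts)
  ref <- spot_cloud_points(grid, spot_channel, fallback = vol, sp, t)
  paths <- list()
  for (cc in unique(lab)) {
    cv <- vox[lab == cc, , drop = FALSE]
    if (split_junctions) {
      pp <- extract_component_paths(cv, sp, d, shifts, min_voxels)
      paths <- c(paths, stitch_paths(pp))
    } else if (nrow(cv) >= min_voxels) {
      p <- trace_component_path(cv, sp, shifts)
      if (!is.null(p)) paths <- c(paths, list(p))
    }
  }
  cil <- list(); polys <- list()
  for (path_um in paths) {
    path_um <- smooth_path(path_um, window = 7L)
    path_um <- recenter_path(path_um, sm, sp, base_lvl)
    path_um <- recenter_path(path_um, sm, sp, base_lvl)
    path_um <- refine_filament_ends(path_um, sm, sp, base_lvl)
    len <- polyline_length(path_um)
    if (len < min_length_um) next
    ends <- rbind(path_um[1, ], path_um[nrow(path_um), ])
    dref <- apply(ends, 1, function(e)
      min(sqrt(colSums((t(ref) - e)^2))))
    if (dref[2] < dref[1]) path_um <- path_um[rev(seq_len(nrow(path_um))), ]
    k <- length(cil) + 1L
    cil[[k]] <- data.frame(
      id = k, length_um = len,
      base_z_um = path_um[1, 1], base_y_um = path_um[1, 2],
      base_x_um = path_um[1, 3],
      tip_z_um = path_um[nrow(path_um), 1],
      tip_y_um = path_um[nrow(path_um), 2],
      tip_x_um = path_um[nrow(path_um), 3])
    polys[[k]] <- path_um
  }
  if (length(cil) == 0L) return(empty)
  out <- do.call(rbind, cil)
  rownames(out) <- NULL
  attr(out, "polylines") <- polys
  class(out) <- c("cilium_table", "data.frame")
  out
}

# Bright voxels of the spot channel (the cloud of centriole puncta),
# as physical positions; used to orient filament bases. Falls back to the
# volume's own intensity-weighted centroid when no spot channel exists.
spot_cloud_points <- function(grid, spot_channel, fallback, sp, t,
                              max_points = 4000L) {
  vol <- if (!is.null(spot_channel) &&
             spot_channel %in% grid$channel_names)
    grid_channel(grid, spot_channel, t) else fallback
  v <- as.vector(vol)
  thr <- stats::median(v) + 0.5 * (max(v) - stats::median(v))
  idx <- which(vol > thr, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    w <- pmax(vol - stats::median(vol), 0)
    tot <- sum(w)
    d <- dim(vol)
    if (tot <= 0) return(matrix((d - 1) / 2 * sp, 1))
    gz <- apply(w, 1, sum); gy <- apply(w, 2, sum); gx <- apply(w, 3, sum)
    return(matrix(c(sum((seq_len(d[1]) - 1) * gz),
                    sum((seq_len(d[2]) - 1) * gy),
                    sum((seq_len(d[3]) - 1) * gx)) / tot * sp, 1))
  }
  if (nrow(idx) > max_points)
    idx <- idx[seq(1L, nrow(idx), length.out = max_points), , drop = FALSE]
  cbind((idx[, 1] - 1) * sp[1], (idx[, 2] - 1) * sp[2],
        (idx[, 3] - 1) * sp[3])
}

# Hessian eigenvalues (ascending) of a smoothed volume at sparse voxels,
# by central differences and the closed-form symmetric 3x3 eigensolver.
hessian_eigen_sparse <- function(sm, vox, sp) {
  d <- dim(sm)
  cl <- function(i, n) pmin(pmax(i, 1L), n)
  at <- function(dz, dy, dx)
    sm[cbind(cl(vox[, 1] + dz, d[1]), cl(vox[, 2] + dy, d[2]),
             cl(vox[, 3] + dx, d[3]))]
  v0 <- at(0, 0, 0)
  h <- sp
  a11 <- (at(1, 0, 0) - 2 * v0 + at(-1, 0, 0)) / h[1]^2
  a22 <- (at(0, 1, 0) - 2 * v0 + at(0, -1, 0)) / h[2]^2
  a33 <- (at(0, 0, 1) - 2 * v0 + at(0, 0, -1)) / h[3]^2
  a12 <- (at(1, 1, 0) - at(1, -1, 0) - at(-1, 1, 0) + at(-1, -1, 0)) /
    (4 * h[1] * h[2])
  a13 <- (at(1, 0, 1) - at(1, 0, -1) - at(-1, 0, 1) + at(-1, 0, -1)) /
    (4 * h[1] * h[3])
  a23 <- (at(0, 1, 1) - at(0, 1, -1) - at(0, -1, 1) + at(0, -1, -1)) /
    (4 * h[2] * h[3])
  q <- (a11 + a22 + a33) / 3
  p1 <- a12^2 + a13^2 + a23^2
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2 / 6, 0))
  b11 <- (a11 - q); b22 <- (a22 - q); b33 <- (a33 - q)
  detB <- b11 * (b22 * b33 - a23^2) - a12 * (a12 * b33 - a23 * a13) +
    a13 * (a12 * a23 - b22 * a13)
  r <- ifelse(p > 0, detB / (2 * p^3), 0)
  r <- pmin(pmax(r, -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e3 <- q + 2 * p * cos(phi)
  e2 <- 3 * q - e1 - e3
  cbind(e1, e2, e3)  # ascending
}

# Iterative path extraction from one voxel component: trace the geodesic
# diameter path, remove voxels within the tube radius of it, and recurse
# on what remains, so filaments joined at a junction are still recovered
# as separate paths.
extract_component_paths <- function(cv, sp, dims, shifts, min_voxels,
                                    clear_radius_um = c(0.75, 0.45, 0.45),
                                    depth = 0L) {
  if (nrow(cv) < min_voxels || depth > 5L) return(list())
  path <- trace_component_path(cv, sp, shifts)
  if (is.null(path)) return(list())
  ref <- resample_polyline(path, 0.15)
  # anisotropy-normalized clearance: the mask is thicker along z than in
  # the lateral plane, so the cleared tube must be too
  pts_n <- cbind((cv[, 1] - 1) * sp[1] / clear_radius_um[1],
                 (cv[, 2] - 1) * sp[2] / clear_radius_um[2],
                 (cv[, 3] - 1) * sp[3] / clear_radius_um[3])
  ref_n <- sweep(ref, 2, clear_radius_um, "/")
  d2 <- apply(ref_n, 1, function(q) rowSums(sweep(pts_n, 2, q)^2))
  mind <- sqrt(if (is.matrix(d2)) do.call(pmin, as.data.frame(d2)) else
    min(d2))
  residual <- mind > 1
  out <- list(path)
  if (sum(residual) >= min_voxels) {
    rv <- cv[residual, , drop = FALSE]
    lab <- components_26(rv, dims, shifts)
    for (cc in unique(lab)) {
      sub <- rv[lab == cc, , drop = FALSE]
      out <- c(out, extract_component_paths(sub, sp, dims, shifts,
                                            min_voxels, clear_radius_um,
                                            depth + 1L))
    }
  }
  out
}

# End tangent of a path (unit vector pointing outward at the given end),
# estimated over about `chord_um` of arc.
path_end_tangent <- function(path, end, chord_um = 0.5) {
  n <- nrow(path)
  cl <- polyline_cumlen(path)
  if (end == 1L) {
    j <- which(cl >= min(chord_um, cl[n] / 2))[1]
    v <- path[1, ] - path[max(j, 2L), ]
  } else {
    j <- which(cl >= cl[n] - min(chord_um, cl[n] / 2))[1]
    v <- path[n, ] - path[min(j, n - 1L), ]
  }
  v / max(sqrt(sum(v^2)), 1e-12)
}

# Stitch path fragments severed at filament junctions: ends of different
# fragments that are close and continue each other (outward tangents
# anti-parallel) are greedily rejoined, so a filament crossing another is
# recovered whole rather than as two arms.
stitch_paths <- function(paths, join_radius_um = 1.7, cos_max = -0.7,
                         max_iter = 20L) {
  for (it in seq_len(max_iter)) {
    if (length(paths) < 2L) return(paths)
    ends <- list()
    for (i in seq_along(paths)) for (e in 1:2) {
      p <- paths[[i]]
      pt <- if (e == 1L) p[1, ] else p[nrow(p), ]
      ends[[length(ends) + 1L]] <-
        list(path = i, end = e, pt = pt,
             tangent = path_end_tangent(p, e))
    }
    best <- NULL; best_score <- Inf
    for (a in seq_along(ends)) for (b in seq_along(ends)) {
      if (b <= a) next
      ea <- ends[[a]]; eb <- ends[[b]]
      if (ea$path == eb$path) next
      dd <- sqrt(sum((ea$pt - eb$pt)^2))
      if (dd > join_radius_um) next
      cs <- sum(ea$tangent * eb$tangent)
      if (cs > cos_max) next
      score <- dd + (1 + cs)
      if (score < best_score) { best_score <- score; best <- list(ea, eb) }
    }
    if (is.null(best)) return(paths)
    pa <- paths[[best[[1]]$path]]; pb <- paths[[best[[2]]$path]]
    if (best[[1]]$end == 1L) pa <- pa[rev(seq_len(nrow(pa))), , drop = FALSE]
    if (best[[2]]$end == 2L) pb <- pb[rev(seq_len(nrow(pb))), , drop = FALSE]
    joined <- rbind(pa, pb)
    paths <- c(paths[-c(best[[1]]$path, best[[2]]$path)], list(joined))
  }
  paths
}

# Geodesic diameter path of a voxel component: double Dijkstra sweep over
# the 26-adjacency graph with physical edge lengths.
trace_component_path <- function(cv, sp, shifts = neighbor_shifts()) {
  n <- nrow(cv)
  if (n < 2L) return(NULL)
  # physical coordinates (voxel-center convention, 0-based indices)
  pts_um <- cbind((cv[, 1] - 1) * sp[1], (cv[, 2] - 1) * sp[2],
                  (cv[, 3] - 1) * sp[3])
  # neighbour pairs found by matching shifted linear indices
  dims <- c(max(cv[, 1]) + 2L, max(cv[, 2]) + 2L, max(cv[, 3]) + 2L)
  lin <- (cv[, 3] - 1) * (dims[1] * dims[2]) + (cv[, 2] - 1) * dims[1] +
    cv[, 1]
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  for (s in seq_len(nrow(shifts))) {
    slin <- lin + shifts[s, 1] + shifts[s, 2] * dims[1] +
      shifts[s, 3] * dims[1] * dims[2]
    hit <- match(slin, lin)
    ok <- !is.na(hit)
    if (!any(ok)) next
    from <- c(from, which(ok)); to <- c(to, hit[ok])
    wt <- c(wt, rep(sqrt(sum((shifts[s, ] * sp)^2)), sum(ok)))
  }
  if (length(from) == 0L) return(NULL)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  igraph::E(g)$weight <- wt
  dists <- igraph::distances(g, v = 1)
  e1 <- which.max(ifelse(is.finite(dists), dists, -1))
  dists <- igraph::distances(g, v = e1)
  e2 <- which.max(ifelse(is.finite(dists), dists, -1))
  pth <- igraph::shortest_paths(g, from = e1, to = e2)$vpath[[1]]
  idx <- as.integer(pth)
  if (length(idx) < 2L) return(NULL)
  pts_um[idx, , drop = FALSE]
}

# Recenter each path sample onto the intensity centroid of its
# perpendicular plane, pulling a geodesic trace (which may cut across the
# blur envelope) back onto the filament axis.
recenter_path <- function(path, sm, sp, base_lvl, radius_um = 0.55,
                          step_um = 0.15) {
  path <- resample_polyline(path, step_um)
  n <- nrow(path)
  if (n < 3L) return(path)
  tang <- rbind(path[2, ] - path[1, ],
                path[seq(3, n), , drop = FALSE] -
                  path[seq(1, n - 2), , drop = FALSE],
                path[n, ] - path[n - 1, ])
  tang <- tang / pmax(sqrt(rowSums(tang^2)), 1e-12)
  # in-plane offset grid
  og <- expand.grid(a = seq(-radius_um, radius_um, by = 0.1),
                    b = seq(-radius_um, radius_um, by = 0.1))
  og <- og[og$a^2 + og$b^2 <= radius_um^2, ]
  out <- path
  for (i in seq_len(n)) {
    t1 <- tang[i, ]
    ref <- if (abs(t1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u <- ref - sum(ref * t1) * t1
    u <- u / sqrt(sum(u^2))
    v <- c(t1[2] * u[3] - t1[3] * u[2],
           t1[3] * u[1] - t1[1] * u[3],
           t1[1] * u[2] - t1[2] * u[1])
    pts <- sweep(outer(og$a, u) + outer(og$b, v), 2, path[i, ], "+")
    w <- pmax(interp3(sm, pts, sp) - base_lvl, 0)
    tot <- sum(w)
    if (tot > 0) out[i, ] <- colSums(pts * w) / tot
  }
  smooth_path(out, window = 5L)
}

# Moving-average smoothing of a path's coordinates (ends kept).
smooth_path <- function(pts, window = 7L) {
  n <- nrow(pts)
  if (n <= window) return(pts)
  half <- window %/% 2L
  out <- pts
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    out[i, ] <- colMeans(pts[lo:hi, , drop = FALSE])
  }
  out[1, ] <- pts[1, ]; out[n, ] <- pts[n, ]
  out
}

# Trilinear interpolation of a 3D volume at physical positions.
interp3 <- function(vol, pts_um, sp) {
  d <- dim(vol)
  p <- sweep(rbind(pts_um), 2, sp, "/")  # 0-based voxel coords
  p[, 1] <- pmin(pmax(p[, 1], 0), d[1] - 1)
  p[, 2] <- pmin(pmax(p[, 2], 0), d[2] - 1)
  p[, 3] <- pmin(pmax(p[, 3], 0), d[3] - 1)
  f <- floor(p)
  r <- p - f
  i0 <- f + 1
  val <- 0
  for (bz in 0:1) for (by in 0:1) for (bx in 0:1) {
    wz <- if (bz == 0) 1 - r[, 1] else r[, 1]
    wy <- if (by == 0) 1 - r[, 2] else r[, 2]
    wx <- if (bx == 0) 1 - r[, 3] else r[, 3]
    iz <- pmin(i0[, 1] + bz, d[1]); iy <- pmin(i0[, 2] + by, d[2])
    ix <- pmin(i0[, 3] + bx, d[3])
    val <- val + wz * wy * wx * vol[cbind(iz, iy, ix)]
  }
  val
}

# Trim or extend both filament ends to the half-maximum crossing of the
# intensity profile along the (extended) backbone.
refine_filament_ends <- function(path, sm, sp, base_lvl,
                                 probe_um = 1.2, step_um = 0.05) {
  path <- resample_polyline(path, step_um)
  n <- nrow(path)
  if (n < 5L) return(path)
  plateau <- stats::median(interp3(sm, path, sp))
  half <- base_lvl + 0.5 * (plateau - base_lvl)
  fix_end <- function(path, end) {
    n <- nrow(path)
    if (end == 1L) path <- path[rev(seq_len(n)), , drop = FALSE]
    # now the end of interest is the last row
    tangent <- path[n, ] - path[max(1, n - 5L), ]
    tl <- sqrt(sum(tangent^2))
    if (tl == 0) return(if (end == 1L) path[rev(seq_len(n)), ] else path)
    tangent <- tangent / tl
    s_ext <- seq(step_um, probe_um, by = step_um)
    ext <- sweep(outer(s_ext, tangent), 2, path[n, ], "+")
    prof_in <- interp3(sm, path, sp)
    prof_ext <- interp3(sm, ext, sp)
    prof <- c(prof_in, prof_ext)
    all_pts <- rbind(path, ext)
    # last index from the interior where the profile is still above half
    above <- prof >= half
    # walk from the interior outward; stop at first drop below half
    stop_at <- n
    for (i in seq(n - 4L, length(prof))) {
      if (!above[i]) { stop_at <- i - 1L; break }
      stop_at <- i
    }
    newp <- all_pts[seq_len(max(stop_at, 2L)), , drop = FALSE]
    if (end == 1L) newp[rev(seq_len(nrow(newp))), , drop = FALSE] else newp
  }
  path <- fix_end(path, 2L)
  path <- fix_end(path, 1L)
  path
}

#' Associate cilia with centriole spots
#'
#' One-to-one matching of cilium bases to spots minimizing total
#' base-to-spot distance among pairs within `capture_radius_um` (optimal
#' assignment via the Hungarian algorithm).
#'
#' @param spots a `spot_table`.
#' @param cilia a `cilium_table`.
#' @param capture_radius_um maximum base-to-spot distance for a match.
#' @return an `association_result`: list with `pairs` (spot_id,
#'   cilium_id, distance_um), `n_spots`, `n_cilia`, `fraction_associated`.
#' @export
associate <- function(spots, cilia, capture_radius_um = 0.5) {
  ns <- nrow(spots); nc <- nrow(cilia)
  pairs <- data.frame(spot_id = integer(0), cilium_id = integer(0),
                      distance_um = numeric(0))
  if (ns > 0L && nc > 0L) {
    sm <- as.matrix(spots[, c("z_um", "y_um", "x_um")])
    cm <- as.matrix(cilia[, c("base_z_um", "base_y_um", "base_x_um")])
    cost <- matrix(Inf, ns, nc)
    for (j in seq_len(nc)) {
      dd <- sqrt(rowSums(sweep(sm, 2, cm[j, ])^2))
      cost[dd <= capture_radius_um, j] <- dd[dd <= capture_radius_um]
    }
    asg <- solve_assignment(cost)
    for (i in seq_len(ns)) if (!is.na(asg[i]))
      pairs <- rbind(pairs, data.frame(
        spot_id = spots$id[i], cilium_id = cilia$id[asg[i]],
        distance_um = cost[i, asg[i]]))
  }
  structure(list(pairs = pairs, n_spots = ns, n_cilia = nc,
                 fraction_associated = if (ns > 0) nrow(pairs) / ns else 0),
            class = "association_result")
}

#' @export
print.association_result <- function(x, ...) {
  cat(sprintf(
    "<association_result> %d/%d spots matched to %d cilia (fraction %.3f)\n",
    nrow(x$pairs), x$n_spots, x$n_cilia, x$fraction_associated))
  invisible(x)
}
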