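# Grouping: cluster detected centrioles into migrating groups and
# singletons by single-linkage clustering at a physical cutoff, and
# measure each group's lag behind the dendrite tip along a dendrite path.

#' Cluster spots into centriole groups and singletons
#'
#' Single-linkage clustering at `linkage_cutoff_um`: two spots belong to
#' the same cluster iff they are connected by a chain of pairwise
#' distances at or below the cutoff. Clusters with at least
#' `min_group_size` members become groups (ids 0, 1, ... ordered from
#' apical to basal centroid position); spots in smaller clusters are
#' singletons and carry group id -1.
#'
#' @param spots a `spot_table` (or data.frame with z_um, y_um, x_um).
#' @param linkage_cutoff_um linkage distance cutoff, micrometres.
#' @param min_group_size minimum members for a cluster to count as a group.
#' @param apical_axis apical convention used to order groups (as in
#'   [voxel_grid()]).
#' @return a list with `groups` (data.frame: group_id, size, centroid
#'   coordinates, extent_um), `membership` (per-spot group id, -1 for
#'   singletons) and `singletons` (spot ids).
#' @export
cluster_groups <- function(spots, linkage_cutoff_um = 2,
                           min_group_size = 2L,
                           apical_axis = list(axis = "z", sign = -1)) {
  if (linkage_cutoff_um <= 0)
    stop("'linkage_cutoff_um' must be positive", call. = FALSE)
  n <- nrow(spots)
  gdf <- data.frame(group_id = integer(0), size = integer(0),
                    centroid_z_um = numeric(0), centroid_y_um = numeric(0),
                    centroid_x_um = numeric(0), extent_um = numeric(0))
  if (n == 0L)
    return(list(groups = gdf, membership = integer(0),
                singletons = integer(0)))
  pos <- as.matrix(spots[, c("z_um", "y_um", "x_um")])
  cl <- if (n == 1L) 1L else {
    hc <- stats::hclust(stats::dist(pos), method = "single")
    stats::cutree(hc, h = linkage_cutoff_um)
  }
  sizes <- table(cl)
  group_cl <- as.integer(names(sizes)[sizes >= min_group_size])
  # order groups apical-first by centroid
  ax <- match(apical_axis$axis, c("z", "y", "x"))
  cent <- t(vapply(group_cl, function(g)
    colMeans(pos[cl == g, , drop = FALSE]), numeric(3)))
  if (length(group_cl) > 0L) {
    ord <- order(-apical_axis$sign * cent[, ax])
    group_cl <- group_cl[ord]
    cent <- cent[ord, , drop = FALSE]
  }
  membership <- rep(-1L, n)
  rows <- list()
  for (k in seq_along(group_cl)) {
    idx <- which(cl == group_cl[k])
    membership[idx] <- k - 1L
    pp <- pos[idx, , drop = FALSE]
    ext <- if (length(idx) > 1L) max(stats::dist(pp)) else 0
    rows[[k]] <- data.frame(
      group_id = k - 1L, size = length(idx),
      centroid_z_um = cent[k, 1], centroid_y_um = cent[k, 2],
      centroid_x_um = cent[k, 3], extent_um = ext)
  }
  if (length(rows) > 0L) gdf <- do.call(rbind, rows)
  ids <- if ("id" %in% names(spots)) spots$id else seq_len(n)
  list(groups = gdf, membership = membership,
       singletons = ids[membership == -1L])
}

#' Measure a group's lag behind the dendrite tip
#'
#' The group centroid is projected orthogonally onto the dendrite path
#' polyline; the lag is the arc distance from the projection to the
#' path's apical endpoint (its last vertex).
#'
#' @param group one row of the `groups` data.frame from
#'   [cluster_groups()], or any list with `centroid_z_um`,
#'   `centroid_y_um`, `centroid_x_um`.
#' @param dendrite_path_um polyline matrix (rows = vertices, columns
#'   z_um, y_um, x_um), ordered base to apical tip.
#' @param projection_tolerance_um maximum allowed centroid-to-path
#'   distance.
#' @return a list with `group_id`, `tip_um`, `lag_um`.
#' @export
measure_lag <- function(group, dendrite_path_um,
                        projection_tolerance_um = 2) {
  pts <- as.matrix(dendrite_path_um)
  q <- c(group$centroid_z_um, group$centroid_y_um, group$centroid_x_um)
  pr <- polyline_project(pts, q)
  if (pr$dist > projection_tolerance_um)
    stop(sprintf(
      "group centroid lies %.2f um from the dendrite path (tolerance %g)",
      pr$dist, projection_tolerance_um), call. = FALSE)
  total <- polyline_length(pts)
  list(group_id = if (!is.null(group$group_id)) group$group_id else NA,
       tip_um = pts[nrow(pts), ], lag_um = total - pr$arc)
}
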