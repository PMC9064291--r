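# VoxelGrid: the carrier of all image data. A 5D intensity array with
# axes (t, c, z, y, x), physical voxel spacing for the spatial axes, channel
# names, and the apical-axis convention used throughout the package.

#' Construct a VoxelGrid
#'
#' A `voxel_grid` wraps a multi-channel, optionally time-indexed intensity
#' array with physical calibration. Axes are ordered (t, c, z, y, x);
#' singleton axes are allowed and arrays of lower dimensionality are
#' promoted by prepending singleton axes. Physical coordinates are
#' 0-based voxel index times spacing (voxel-center convention). "Apical"
#' is the direction of decreasing z unless overridden.
#'
#' @param data numeric array with 3 (z,y,x), 4 (c,z,y,x) or 5 (t,c,z,y,x)
#'   dimensions.
#' @param spacing_um physical spacing in micrometres for (z, y, x).
#' @param channel_names character vector, one name per channel.
#' @param apical_axis list with elements `axis` (one of "z","y","x") and
#'   `sign` (+1 or -1): apical lies in the direction of `sign` times
#'   increasing coordinate. Default: decreasing z.
#' @return an object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, spacing_um = c(0.27, 0.11, 0.11),
                       channel_names = NULL,
                       apical_axis = list(axis = "z", sign = -1)) {
  nd <- length(dim(data))
  if (is.null(dim(data)) || nd < 3L || nd > 5L)
    stop("'data' must be a 3D, 4D or 5D array", call. = FALSE)
  if (nd == 3L) dim(data) <- c(1L, 1L, dim(data))
  if (nd == 4L) dim(data) <- c(1L, dim(data))
  spacing_um <- as.numeric(spacing_um)
  if (length(spacing_um) != 3L) stop("'spacing_um' must have length 3 (z,y,x)",
                                     call. = FALSE)
  assert_positive(spacing_um, "spacing_um")
  nc <- dim(data)[2]
  if (is.null(channel_names))
    channel_names <- paste0("ch", seq_len(nc) - 1L)
  if (length(channel_names) != nc)
    stop("length(channel_names) must equal the channel-axis extent",
         call. = FALSE)
  if (!apical_axis$axis %in% c("z", "y", "x") ||
      !apical_axis$sign %in% c(-1, 1))
    stop("invalid 'apical_axis'", call. = FALSE)
  structure(list(data = data, spacing_um = spacing_um,
                 channel_names = as.character(channel_names),
                 apical_axis = apical_axis),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<voxel_grid> %d t x %d c x %d z x %d y x %d x\n",
              d[1], d[2], d[3], d[4], d[5]))
  cat(sprintf("  spacing (z,y,x): %s um\n",
              paste(signif(x$spacing_um, 4), collapse = " x ")))
  cat(sprintf("  channels: %s\n", paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  apical: %s %s\n",
              if (x$apical_axis$sign < 0) "decreasing" else "increasing",
              x$apical_axis$axis))
  invisible(x)
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

# Extract one channel at one timepoint as a plain 3D (z,y,x) array.
grid_channel <- function(grid, channel, t = 1L) {
  ci <- if (is.character(channel)) match(channel, grid$channel_names)
        else as.integer(channel)
  if (is.na(ci) || ci < 1L || ci > dim(grid$data)[2])
    stop(sprintf("channel '%s' not found", channel), call. = FALSE)
  a <- grid$data[t, ci, , , ]
  dim(a) <- dim(grid$data)[3:5]
  a
}

# Signed apical coordinate of physical positions (rows z_um,y_um,x_um):
# larger value = more apical.
apical_coordinate <- function(grid, pos_um) {
  pos_um <- rbind(pos_um)
  ax <- match(grid$apical_axis$axis, c("z", "y", "x"))
  grid$apical_axis$sign * pos_um[, ax]
}

#' Write a VoxelGrid to a multi-page TIFF with a YAML sidecar manifest
#'
#' Pages are written in TZC order (t slowest, then z, then c), each page a
#' (y, x) plane of 32-bit floats. Intensities are rescaled to the unit
#' interval for storage; the scale and offset, axis extents, spacing,
#' channel names and apical convention are stored in `<path>.yaml` so that
#' [read_stack()] round-trips the grid exactly.
#'
#' @param grid a `voxel_grid`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  lo <- min(grid$data); hi <- max(grid$data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- vector("list", d[1] * d[3] * d[2])
  k <- 0L
  for (t in seq_len(d[1])) for (z in seq_len(d[3])) for (c in seq_len(d[2])) {
    k <- k + 1L
    pl <- (grid$data[t, c, z, , ] - lo) / scale
    dim(pl) <- d[4:5]
    pages[[k]] <- pl
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  manifest <- list(
    axes = "TZCYX",
    shape = list(t = d[1], c = d[2], z = d[3], y = d[4], x = d[5]),
    spacing_um = list(z = grid$spacing_um[1], y = grid$spacing_um[2],
                      x = grid$spacing_um[3]),
    channel_names = as.list(grid$channel_names),
    apical_axis = grid$apical_axis,
    intensity_offset = lo, intensity_scale = scale)
  yaml::write_yaml(manifest, paste0(path, ".yaml"))
  invisible(path)
}

#' Read a TIFF stack into a VoxelGrid
#'
#' Reads a multi-page TIFF. If a `<path>.yaml` sidecar manifest written by
#' [write_stack()] is present, axis extents, spacing and intensity scaling
#' are restored exactly. Otherwise the pages are treated as z-planes of a
#' single channel and timepoint, and spacing falls back to
#' `default_spacing_um` with a warning.
#'
#' @param path TIFF file path.
#' @param default_spacing_um spacing assumed when no manifest is found.
#' @return a `voxel_grid`.
#' @export
read_stack <- function(path, default_spacing_um = c(0.27, 0.11, 0.11)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e)
                      stop(sprintf("cannot read TIFF '%s': %s", path,
                                   conditionMessage(e)), call. = FALSE))
  if (is.matrix(pages)) pages <- list(pages)
  npg <- length(pages)
  man_path <- paste0(path, ".yaml")
  if (file.exists(man_path)) {
    man <- yaml::read_yaml(man_path)
    sh <- man$shape
    if (sh$t * sh$z * sh$c != npg)
      stop(sprintf("manifest shape (%d pages) disagrees with TIFF (%d pages)",
                   sh$t * sh$z * sh$c, npg), call. = FALSE)
    a <- array(0, dim = c(sh$t, sh$c, sh$z, sh$y, sh$x))
    k <- 0L
    for (t in seq_len(sh$t)) for (z in seq_len(sh$z)) for (c in seq_len(sh$c)) {
      k <- k + 1L
      a[t, c, z, , ] <- pages[[k]]
    }
    a <- a * man$intensity_scale + man$intensity_offset
    voxel_grid(a,
               spacing_um = c(man$spacing_um$z, man$spacing_um$y,
                              man$spacing_um$x),
               channel_names = unlist(man$channel_names),
               apical_axis = list(axis = man$apical_axis$axis,
                                  sign = man$apical_axis$sign))
  } else {
    warning(sprintf(
      "no manifest for '%s'; assuming single channel/timepoint and spacing %s",
      path, paste(default_spacing_um, collapse = "/")), call. = FALSE)
    a <- array(0, dim = c(1L, 1L, npg, nrow(pages[[1]]), ncol(pages[[1]])))
    for (z in seq_len(npg)) a[1, 1, z, , ] <- pages[[z]]
    voxel_grid(a, spacing_um = default_spacing_um)
  }
}
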