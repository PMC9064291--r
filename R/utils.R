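# Internal numerical helpers: seeded RNG scoping, separable Gaussian
# filtering on 3D arrays, thresholding, connected components, and a
# small dense Hungarian solver for one-to-one assignment.

#' Evaluate an expression with a locally seeded RNG
#'
#' Sets the RNG seed for the duration of `expr` and restores the previous
#' global RNG state afterwards, so generators never leak RNG state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stage name, keeping the
# result a valid 32-bit R integer. Used so one pipeline seed gives
# independent, rerunnable per-stage streams.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

# --- separable filtering -------------------------------------------------

gaussian_kernel_1d <- function(sigma_vox, radius = NULL) {
  if (sigma_vox <= 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(3 * sigma_vox))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with a short kernel, replicating
# edges (kernel renormalized near the boundary). Implemented as a banded
# matrix product so BLAS does the work.
conv_axis3 <- function(a, axis, kernel) {
  if (length(kernel) == 1L) return(a * kernel)
  d <- dim(a)
  n <- d[axis]
  r <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    idx <- (j - r):(j + r)
    w <- kernel
    keep <- idx >= 1L & idx <= n
    w <- w[keep] / sum(kernel[keep])
    K[idx[keep], j] <- K[idx[keep], j] + w
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- dim(ap)
  res <- crossprod(K, matrix(ap, nrow = n))
  dim(res) <- m
  aperm(res, order(perm))
}

# Smooth a 3D array with an anisotropic Gaussian given in voxel units.
gauss_smooth3 <- function(a, sigma_vox) {
  for (ax in 1:3) a <- conv_axis3(a, ax, gaussian_kernel_1d(sigma_vox[ax]))
  a
}

# Second difference along one axis (replicated edges), divided by h^2.
second_diff3 <- function(a, axis, h) {
  d <- dim(a)
  n <- d[axis]
  up <- pmin(seq_len(n) + 1L, n)
  dn <- pmax(seq_len(n) - 1L, 1L)
  idx_take <- function(i) {
    switch(axis, a[i, , , drop = FALSE], a[, i, , drop = FALSE],
           a[, , i, drop = FALSE])
  }
  (idx_take(up) - 2 * a + idx_take(dn)) / h^2
}

# --- thresholding --------------------------------------------------------

# Otsu threshold of a numeric vector (delegated to EBImage on a
# normalized copy). Returns the threshold on the original scale.
otsu_threshold <- function(v) {
  v <- v[is.finite(v)]
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(hi)
  x <- (v - lo) / (hi - lo)
  t <- EBImage::otsu(EBImage::Image(matrix(x, nrow = 1L)),
                     range = c(0, 1), levels = 256L)
  lo + t * (hi - lo)
}

# Robust noise scale (MAD about the median).
noise_sigma <- function(v) stats::mad(v, constant = 1.4826)

# --- connected components ------------------------------------------------

# Half-set of neighbourhood shifts within a per-axis radius (each
# unordered pair of voxels is visited once).
neighbor_shifts <- function(rz = 1L, ry = 1L, rx = 1L) {
  shifts <- as.matrix(expand.grid(dz = -rz:rz, dy = -ry:ry, dx = -rx:rx))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  shifts[1:(nrow(shifts) / 2), , drop = FALSE]
}

# Connected components of a sparse voxel set given as an integer index
# matrix (rows = voxels, cols = z,y,x indices) within an array of
# dimensions `dims`, using the supplied neighbourhood shifts (default
# 26-connectivity). Returns a label vector (1-based component ids).
# Neighbour pairs found by vectorized linear-index matching; components
# via igraph.
components_26 <- function(vox, dims, shifts = neighbor_shifts()) {
  n <- nrow(vox)
  if (n == 0L) return(integer(0))
  lin <- (vox[, 3] - 1) * (dims[1] * dims[2]) + (vox[, 2] - 1) * dims[1] +
    vox[, 1]
  id <- seq_len(n)
  from <- integer(0); to <- integer(0)
  for (s in seq_len(nrow(shifts))) {
    sz <- vox[, 1] + shifts[s, 1]
    sy <- vox[, 2] + shifts[s, 2]
    sx <- vox[, 3] + shifts[s, 3]
    inb <- sz >= 1L & sz <= dims[1] & sy >= 1L & sy <= dims[2] &
      sx >= 1L & sx <= dims[3]
    slin <- (sx[inb] - 1) * (dims[1] * dims[2]) + (sy[inb] - 1) * dims[1] +
      sz[inb]
    hit <- match(slin, lin)
    ok <- !is.na(hit)
    from <- c(from, id[inb][ok]); to <- c(to, hit[ok])
  }
  if (length(from) == 0L) return(id)
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  as.integer(comp$membership[id])
}

# --- assignment ----------------------------------------------------------

#' Minimum-cost one-to-one assignment (Hungarian algorithm)
#'
#' Dense O(n^3) shortest augmenting path implementation for small
#' rectangular cost matrices. Returns, for each row, the assigned column
#' index or NA. No assignment is forced through entries equal to `Inf`.
#'
#' @param cost numeric matrix of costs (may contain Inf for forbidden pairs).
#' @return integer vector, length nrow(cost).
#' @noRd
solve_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  if (nr == 0L || nc == 0L) return(rep(NA_integer_, nr))
  transposed <- FALSE
  if (nr > nc) { cost <- t(cost); transposed <- TRUE }
  n <- nrow(cost); m <- ncol(cost)
  BIG <- sum(cost[is.finite(cost)]) + 1
  if (!is.finite(BIG)) BIG <- 1
  a <- cost
  a[!is.finite(a)] <- BIG
  # JV-style shortest augmenting path with potentials
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)  # p[j] = row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[m + 1] <- i
    j0 <- m + 1
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    prev <- integer(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- a[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; prev[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- prev[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1) break
    }
  }
  row_of_col <- p[seq_len(m)]
  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (row_of_col[j] > 0L) assign_row[row_of_col[j]] <- j
  # drop forbidden matches
  for (i in seq_len(n))
    if (!is.na(assign_row[i]) && !is.finite(cost[i, assign_row[i]]))
      assign_row[i] <- NA_integer_
  if (transposed) {
    out <- rep(NA_integer_, nc)
    for (i in seq_len(n)) if (!is.na(assign_row[i])) out[assign_row[i]] <- i
    out
  } else assign_row
}

# --- polylines -----------------------------------------------------------

#' Arc length of a polyline
#'
#' @param pts numeric matrix, one vertex per row (any dimension).
#' @return total Euclidean arc length.
#' @export
polyline_length <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                    pts[-nrow(pts), , drop = FALSE])^2)))
}

# Cumulative arc position of each vertex.
polyline_cumlen <- function(pts) {
  pts <- as.matrix(pts)
  c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] -
                            pts[-nrow(pts), , drop = FALSE])^2))))
}

# Orthogonal projection of a point onto a polyline: returns the arc
# position and distance of the closest point on any segment.
polyline_project <- function(pts, q) {
  pts <- as.matrix(pts)
  cl <- polyline_cumlen(pts)
  best <- list(dist = Inf, arc = 0)
  for (i in seq_len(nrow(pts) - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) 0 else max(0, min(1, sum((q - a) * ab) / len2))
    pr <- a + t * ab
    d <- sqrt(sum((q - pr)^2))
    if (d < best$dist) best <- list(dist = d, arc = cl[i] + t * sqrt(len2))
  }
  best
}

# Linear interpolation of a polyline's ordinate at a lateral position x.
# pts has columns (x, y); x must lie within the vertex span.
polyline_interp_y <- function(pts, x) {
  pts <- as.matrix(pts)
  o <- order(pts[, 1])
  stats::approx(pts[o, 1], pts[o, 2], xout = x, rule = 1)$y
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x) & !is.infinite(x)) || any(x <= 0))
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  invisible(x)
}
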