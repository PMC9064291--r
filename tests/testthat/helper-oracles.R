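# Shared oracles and small fixture builders, independent of the package
# internals they are used to check.

# Brute-force minimum-cost one-to-one assignment by enumerating all
# injections of the smaller side into the larger (feasible up to ~6x6).
brute_force_assignment <- function(cost) {
  nr <- nrow(cost); nc <- ncol(cost)
  best_cost <- Inf
  k <- min(nr, nc)
  # enumerate over subsets and permutations of columns assigned to rows
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  combs <- utils::combn(max(nr, nc), k, simplify = FALSE)
  for (cols in combs) for (p in perms(cols)) {
    if (nr <= nc) {
      cc <- cost[cbind(seq_len(nr), p)]
    } else {
      cc <- cost[cbind(p, seq_len(nc))]
    }
    cc <- cc[is.finite(cc)]
    tot <- sum(cc)
    n_matched <- length(cc)
    # lexicographic objective: maximize matches within radius, then cost
    score <- -n_matched * 1e9 + tot
    if (score < best_cost - 1e-12) best_cost <- score
  }
  best_cost
}

# Union-find single-linkage partition: connected components of the graph
# with edges between all pairs at distance <= cutoff.
brute_force_single_linkage <- function(pos, cutoff) {
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Normalize a partition label vector to a canonical form so two
# partitions can be compared regardless of label names.
canonical_partition <- function(labels) {
  match(labels, unique(labels))
}

# Exhaustive sign-flip null distribution of the mean paired difference.
brute_force_signflip_p <- function(d, alternative = "two.sided") {
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  tstar <- as.vector(signs %*% d) / n
  tobs <- mean(d)
  eps <- 1e-12
  switch(alternative,
         two.sided = mean(abs(tstar) >= abs(tobs) - eps),
         greater = mean(tstar >= tobs - eps),
         less = mean(tstar <= tobs + eps))
}

# Small deterministic spot table builder.
make_spots <- function(pos) {
  pos <- rbind(pos)
  n <- nrow(pos)
  data.frame(id = seq_len(n),
             z_um = as.numeric(pos[, 1]), y_um = as.numeric(pos[, 2]),
             x_um = as.numeric(pos[, 3]), scale_um = rep(0.3, n),
             intensity = rep(1, n), roi_id = rep(NA_integer_, n))
}

# Cilium table from explicit base/tip coordinates.
make_cilia <- function(bases, tips = NULL) {
  bases <- rbind(bases)
  if (is.null(tips)) tips <- bases + matrix(rep(c(-3, 0, 0),
                                                each = nrow(bases)), ncol = 3)
  data.frame(id = seq_len(nrow(bases)), length_um = 3,
             base_z_um = bases[, 1], base_y_um = bases[, 2],
             base_x_um = bases[, 3], tip_z_um = tips[, 1],
             tip_y_um = tips[, 2], tip_x_um = tips[, 3])
}

# Three-line horizontal annotation over x in [0, span].
flat_annotation <- function(y_apical = 0, y_sust = 20, y_basal = 60,
                            span = 100) {
  epithelium_annotation(
    apical_surface = cbind(c(0, span), c(y_apical, y_apical)),
    sustentacular_lower_boundary = cbind(c(0, span), c(y_sust, y_sust)),
    basal_lamina = cbind(c(0, span), c(y_basal, y_basal)))
}

# Per-frame group tables from a time-lapse ground truth.
truth_frame_groups <- function(truth) {
  cent <- truth$track_centroids_um
  lapply(seq_len(dim(cent)[1]), function(f)
    data.frame(centroid_z_um = cent[f, , 1],
               centroid_y_um = cent[f, , 2],
               centroid_x_um = cent[f, , 3]))
}
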