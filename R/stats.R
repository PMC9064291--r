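# Summary statistics, fold changes, traversal-time arithmetic, and the
# paired sign-flip permutation test for drug versus control count tables.

#' Summary statistics of a measurement vector
#'
#' Mean, sample standard deviation (n - 1 denominator) and standard error
#' of the mean (SD / sqrt(n)). With a single observation SD and SEM are
#' returned as `NA` and flagged.
#'
#' @param values numeric vector (length >= 1).
#' @return a list of class `summary_stats`: n, mean, sd, sem,
#'   `sd_defined`.
#' @export
summary_stats <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("'values' must be non-empty", call. = FALSE)
  n <- length(values)
  s <- if (n >= 2L) stats::sd(values) else NA_real_
  structure(list(n = n, mean = mean(values), sd = s,
                 sem = if (n >= 2L) s / sqrt(n) else NA_real_,
                 sd_defined = n >= 2L),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.4g", x$n, x$mean))
  if (x$sd_defined)
    cat(sprintf(", SD = %.4g, SEM = %.4g", x$sd, x$sem))
  else cat(" (SD/SEM undefined for n = 1)")
  cat("\n")
  invisible(x)
}

#' Standard error of the mean from a standard deviation
#'
#' @param sd sample standard deviation.
#' @param n sample size (>= 1).
#' @return `sd / sqrt(n)`.
#' @export
sem <- function(sd, n) {
  if (n < 1) stop("'n' must be >= 1", call. = FALSE)
  sd / sqrt(n)
}

#' Paired sign-flip permutation test
#'
#' Tests whether the mean paired difference (drug - control) differs from
#' zero. The null distribution is generated by independently flipping each
#' pair's labels; when `2^n_pairs <= n_resamples` every sign pattern is
#' enumerated (exact mode), otherwise `n_resamples` random patterns are
#' drawn and the add-one Monte-Carlo estimate
#' `(1 + #{|T*| >= |T|}) / (1 + B)` is used, so the p-value is never zero.
#' Comparisons use a 1e-12 tolerance so ties are counted as extreme.
#'
#' @param pairs two-column matrix or data.frame: column 1 drug values,
#'   column 2 control values (normalized counts per 100 um).
#' @param n_resamples Monte-Carlo resamples (default 10000).
#' @param seed RNG seed for Monte-Carlo mode.
#' @param alternative `"two.sided"` (by |T|), `"greater"` or `"less"`.
#' @return an object of class `paired_permutation`: observed_stat,
#'   n_pairs, n_resamples, p_value, exact, seed, alternative, statistic
#'   name.
#' @export
paired_permutation_test <- function(pairs, n_resamples = 10000L, seed = 1L,
                                    alternative = c("two.sided", "greater",
                                                    "less")) {
  alternative <- match.arg(alternative)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L)
    stop("'pairs' must have two columns (drug, control)", call. = FALSE)
  if (anyNA(pairs))
    stop("pairs with missing members are not allowed", call. = FALSE)
  n <- nrow(pairs)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- pairs[, 1] - pairs[, 2]
  tobs <- mean(d)
  eps <- 1e-12
  exact <- (2^n) <= n_resamples
  tail_count <- function(tstar) {
    switch(alternative,
           two.sided = abs(tstar) >= abs(tobs) - eps,
           greater = tstar >= tobs - eps,
           less = tstar <= tobs + eps)
  }
  if (exact) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    tstar <- as.vector(signs %*% d) / n
    p <- mean(tail_count(tstar))
  } else {
    p <- with_seed(seed, {
      hits <- 0L
      block <- 2000L
      done <- 0L
      while (done < n_resamples) {
        b <- min(block, n_resamples - done)
        sgn <- matrix(sample(c(-1, 1), b * n, replace = TRUE), b, n)
        tstar <- as.vector(sgn %*% d) / n
        hits <- hits + sum(tail_count(tstar))
        done <- done + b
      }
      (1 + hits) / (1 + n_resamples)
    })
  }
  structure(list(observed_stat = tobs, n_pairs = n,
                 n_resamples = n_resamples, p_value = p, exact = exact,
                 seed = seed, alternative = alternative,
                 statistic = "mean paired difference (drug - control)"),
            class = "paired_permutation")
}

#' @export
print.paired_permutation <- function(x, ...) {
  cat("Paired sign-flip permutation test\n")
  cat(sprintf("  statistic: %s = %.4g (n_pairs = %d)\n", x$statistic,
              x$observed_stat, x$n_pairs))
  cat(sprintf("  p-value (%s): %.4g [%s]\n", x$alternative, x$p_value,
              if (x$exact) "exact enumeration"
              else sprintf("%d resamples, seed %d", x$n_resamples, x$seed)))
  invisible(x)
}

#' Build drug/control pairs from a count table
#'
#' Pairs drug against control rows of a `group_count_table` on a key (by
#' default animal x timepoint x compartment) and returns the two-column
#' matrix of normalized counts expected by [paired_permutation_test()].
#'
#' @param counts a `group_count_table`.
#' @param pair_on character vector of pairing-key columns.
#' @return matrix with columns `drug`, `control`, one row per key.
#' @export
pair_counts <- function(counts,
                        pair_on = c("animal_id", "timepoint",
                                    "compartment")) {
  key <- interaction(counts[pair_on], drop = TRUE)
  out <- NULL
  for (k in levels(key)) {
    sub <- counts[key == k, ]
    dr <- sub$normalized_per_100um[sub$condition == "drug"]
    ct <- sub$normalized_per_100um[sub$condition == "control"]
    if (length(dr) != 1L || length(ct) != 1L)
      stop(sprintf("key '%s' does not have exactly one drug and one control record",
                   k), call. = FALSE)
    out <- rbind(out, c(drug = dr, control = ct))
  }
  rownames(out) <- levels(key)
  out
}

#' Fold change of normalized counts, drug over control
#'
#' @param drug,control single records (rows) of a `group_count_table`
#'   for the same compartment and timepoint.
#' @return ratio of normalized counts.
#' @export
fold_change <- function(drug, control) {
  if (!is.null(drug$compartment) && !is.null(control$compartment) &&
      (drug$compartment != control$compartment ||
       drug$timepoint != control$timepoint))
    stop("fold change requires matching compartment and timepoint",
         call. = FALSE)
  if (control$normalized_per_100um <= 0)
    stop("control normalized count is zero; fold change undefined",
         call. = FALSE)
  drug$normalized_per_100um / control$normalized_per_100um
}

#' Time to traverse a distance at a constant rate
#'
#' @param distance_um distance in micrometres (>= 0).
#' @param rate_um_per_min migration rate in micrometres per minute (> 0).
#' @param digits rounding for reporting (default 2 decimals).
#' @return duration in hours.
#' @export
traversal_time <- function(distance_um, rate_um_per_min, digits = 2L) {
  if (!is.numeric(rate_um_per_min) || rate_um_per_min <= 0)
    stop("'rate_um_per_min' must be positive", call. = FALSE)
  if (distance_um < 0) stop("'distance_um' must be >= 0", call. = FALSE)
  round(distance_um / rate_um_per_min / 60, digits)
}
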