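# Compartment scoring: classify side-view positions into epithelial
# compartments using the landmark annotation, tabulate counts normalized
# to basal-lamina length, and compute linear densities.

#' Classify a side-view position into an epithelial compartment
#'
#' The three landmark polylines are interpolated at the point's lateral
#' coordinate. Intervals are closed on the apical side and a point lying
#' exactly on a boundary belongs to the more apical compartment, so the
#' subapical compartment is `[apical surface, sustentacular boundary]` and
#' the middle/basal compartment is `(sustentacular boundary, basal
#' lamina]`. Positions above the apical surface or below the basal lamina
#' are labelled `"outside"`.
#'
#' @param position_um numeric `(x_um, y_um)` side-view point (y grows
#'   basally).
#' @param annotation an [epithelium_annotation()].
#' @return `"subapical"`, `"middle_basal"` or `"outside"`.
#' @export
classify_compartment <- function(position_um, annotation) {
  x <- position_um[1]; y <- position_um[2]
  span <- annotation_span(annotation)
  if (is.na(x) || x < span[1] || x > span[2])
    stop(sprintf(
      "lateral coordinate %.3f outside the annotated span [%.3f, %.3f]",
      x, span[1], span[2]), call. = FALSE)
  ya <- polyline_interp_y(annotation$apical_surface, x)
  ys <- polyline_interp_y(annotation$sustentacular_lower_boundary, x)
  yb <- polyline_interp_y(annotation$basal_lamina, x)
  if (y >= ya && y <= ys) "subapical"
  else if (y > ys && y <= yb) "middle_basal"
  else "outside"
}

#' Tabulate centriole-group counts per compartment
#'
#' Partitions group positions by [classify_compartment()] and emits one
#' record per compartment with counts normalized per 100 um of
#' basal-lamina arc length.
#'
#' @param groups data.frame with side-view positions `x_um`, `y_um` (one
#'   row per centriole group).
#' @param annotation an [epithelium_annotation()].
#' @param animal_id,condition,timepoint metadata attached to each record.
#' @return a data.frame of class `group_count_table` with one row per
#'   compartment (plus an `"outside"` row when applicable).
#' @export
tabulate_counts <- function(groups, annotation, animal_id = "A1",
                            condition = "control", timepoint = "0h") {
  labels <- if (nrow(groups) > 0L)
    vapply(seq_len(nrow(groups)), function(i)
      classify_compartment(c(groups$x_um[i], groups$y_um[i]), annotation),
      character(1))
  else character(0)
  len <- annotation$basal_length_um
  comps <- c("subapical", "middle_basal")
  rows <- lapply(comps, function(comp) {
    cnt <- sum(labels == comp)
    data.frame(animal_id = animal_id, condition = condition,
               timepoint = timepoint, compartment = comp, count = cnt,
               basal_length_um = len,
               normalized_per_100um = 100 * cnt / len,
               stringsAsFactors = FALSE)
  })
  n_out <- sum(labels == "outside")
  if (n_out > 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      animal_id = animal_id, condition = condition, timepoint = timepoint,
      compartment = "outside", count = n_out, basal_length_um = len,
      normalized_per_100um = 100 * n_out / len, stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  class(out) <- c("group_count_table", "data.frame")
  out
}

#' Linear density per 100 micrometres
#'
#' @param n_objects object count.
#' @param basal_length_um scored basal-lamina arc length (> 0).
#' @param digits rounding for reporting (default 2 decimals).
#' @return `100 * n_objects / basal_length_um`, rounded to `digits`.
#' @export
linear_density <- function(n_objects, basal_length_um, digits = 2L) {
  if (!is.numeric(basal_length_um) || basal_length_um <= 0)
    stop("'basal_length_um' must be positive", call. = FALSE)
  if (n_objects < 0) stop("'n_objects' must be non-negative", call. = FALSE)
  round(100 * n_objects / basal_length_um, digits)
}

#' Read a paired count table from CSV
#'
#' Accepts the per-animal, per-compartment count schema used for drug
#' versus control scoring: columns `animal_id` (or `animal`), `condition`
#' (`drug`/`control`, case-insensitive; `dmso` and `vehicle` are read as
#' control), `timepoint`, `compartment`, `count`, `basal_length_um` (or
#' `length_um`). The normalized column is recomputed from count and
#' length.
#'
#' @param path CSV file path.
#' @return a data.frame of class `group_count_table`.
#' @export
read_count_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  if ("animal" %in% names(tab) && !"animal_id" %in% names(tab))
    names(tab)[names(tab) == "animal"] <- "animal_id"
  if ("length_um" %in% names(tab) && !"basal_length_um" %in% names(tab))
    names(tab)[names(tab) == "length_um"] <- "basal_length_um"
  need <- c("animal_id", "condition", "timepoint", "compartment", "count",
            "basal_length_um")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0L)
    stop(sprintf("count table missing columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  cond <- tolower(tab$condition)
  cond[cond %in% c("dmso", "vehicle", "ctrl", "control")] <- "control"
  cond[cond != "control"] <- "drug"
  tab$condition <- cond
  if (any(tab$basal_length_um <= 0))
    stop("basal_length_um must be positive", call. = FALSE)
  if (any(tab$count < 0)) stop("counts must be non-negative", call. = FALSE)
  tab$normalized_per_100um <- 100 * tab$count / tab$basal_length_um
  out <- tab[, c(need, "normalized_per_100um")]
  class(out) <- c("group_count_table", "data.frame")
  out
}
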