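# Epithelium annotation: three landmark polylines in a 2D side-view frame
# (x = lateral position, y = depth, apical at small y), defining the
# subapical and middle/basal compartments and the basal-lamina arc length
# used to normalize counts.

#' Construct an epithelium annotation
#'
#' Landmarks are polylines in side-view micrometre coordinates with
#' columns (x_um, y_um): `x` runs laterally along the epithelium, `y` runs
#' apico-basally with the apical surface at smaller `y`. At every lateral
#' position where all three are defined the apical surface must lie apical
#' of (not below) the lower boundary of the sustentacular nuclei, which
#' must lie apical of the basal lamina; violations are reported with the
#' offending lateral interval.
#'
#' @param apical_surface,sustentacular_lower_boundary,basal_lamina numeric
#'   matrices (or data frames) with >= 2 rows and columns (x_um, y_um).
#' @return an object of class `epithelium_annotation` with the computed
#'   `basal_length_um`.
#' @export
epithelium_annotation <- function(apical_surface,
                                  sustentacular_lower_boundary,
                                  basal_lamina) {
  as_poly <- function(p, nm) {
    p <- as.matrix(p)
    if (nrow(p) < 2L || ncol(p) != 2L)
      stop(sprintf("'%s' must be a polyline with >= 2 (x, y) vertices", nm),
           call. = FALSE)
    storage.mode(p) <- "double"
    colnames(p) <- c("x_um", "y_um")
    p
  }
  ap <- as_poly(apical_surface, "apical_surface")
  su <- as_poly(sustentacular_lower_boundary, "sustentacular_lower_boundary")
  bl <- as_poly(basal_lamina, "basal_lamina")
  ann <- structure(list(apical_surface = ap,
                        sustentacular_lower_boundary = su,
                        basal_lamina = bl,
                        basal_length_um = polyline_length(bl)),
                   class = "epithelium_annotation")
  validate_annotation(ann)
  ann
}

# Shared lateral span of the three polylines.
annotation_span <- function(ann) {
  c(max(min(ann$apical_surface[, 1]),
        min(ann$sustentacular_lower_boundary[, 1]),
        min(ann$basal_lamina[, 1])),
    min(max(ann$apical_surface[, 1]),
        max(ann$sustentacular_lower_boundary[, 1]),
        max(ann$basal_lamina[, 1])))
}

# Check the apical < sustentacular < basal ordering on a dense lateral
# grid over the shared span; error with the violated interval.
validate_annotation <- function(ann) {
  span <- annotation_span(ann)
  if (span[2] <= span[1])
    stop("annotation polylines share no lateral span", call. = FALSE)
  xs <- seq(span[1], span[2], length.out = 257L)
  ya <- polyline_interp_y(ann$apical_surface, xs)
  ys <- polyline_interp_y(ann$sustentacular_lower_boundary, xs)
  yb <- polyline_interp_y(ann$basal_lamina, xs)
  bad <- which(ya > ys | ys > yb)
  if (length(bad) > 0L)
    stop(sprintf(
      paste0("annotation ordering violated (apical must be above ",
             "sustentacular above basal) over lateral interval ",
             "[%.3f, %.3f] um"),
      min(xs[bad]), max(xs[bad])), call. = FALSE)
  invisible(ann)
}

#' @export
print.epithelium_annotation <- function(x, ...) {
  span <- annotation_span(x)
  cat("<epithelium_annotation>\n")
  cat(sprintf("  lateral span: [%.2f, %.2f] um\n", span[1], span[2]))
  cat(sprintf("  basal lamina length: %.2f um\n", x$basal_length_um))
  invisible(x)
}

#' Load an epithelium annotation from CSV or JSON
#'
#' CSV files must have columns `structure` (one of `apical_surface`,
#' `sustentacular_lower_boundary`, `basal_lamina`), `x_um`, `y_um`, with
#' vertices in order. JSON files must be an object with those three names,
#' each an array of `[x_um, y_um]` vertex pairs. Coordinates are side-view
#' micrometres, apical at smaller `y_um`.
#'
#' @param path file path ending in `.csv` or `.json`.
#' @return an `epithelium_annotation`.
#' @export
load_annotation <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  required <- c("apical_surface", "sustentacular_lower_boundary",
                "basal_lamina")
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    missing <- setdiff(required, names(obj))
    if (length(missing) > 0L)
      stop(sprintf("annotation missing structures: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    polys <- lapply(obj[required], function(p) {
      m <- if (is.matrix(p)) p else do.call(rbind, p)
      matrix(as.numeric(m), ncol = 2)
    })
  } else {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("structure", "x_um", "y_um") %in% names(tab)))
      stop("annotation CSV must have columns structure, x_um, y_um",
           call. = FALSE)
    missing <- setdiff(required, unique(tab$structure))
    if (length(missing) > 0L)
      stop(sprintf("annotation missing structures: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    polys <- lapply(required, function(s)
      as.matrix(tab[tab$structure == s, c("x_um", "y_um")]))
  }
  epithelium_annotation(polys[[1]], polys[[2]], polys[[3]])
}
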