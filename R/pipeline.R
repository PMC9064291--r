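# Pipeline: configuration with defaults for every stage, validation, and
# an end-to-end demo run wiring simulate -> detect -> group -> track ->
# score -> test, with all outputs and the serialized config written for
# provenance.

#' Default run configuration
#'
#' Returns the full nested parameter set for every stage. Any subset of
#' the same structure (e.g. parsed from YAML) can be merged over the
#' defaults with [read_run_config()]. A fully defaulted configuration runs
#' the demo end to end.
#'
#' @param seed global seed; per-stage seeds are derived from it
#'   deterministically so stages can be rerun in isolation.
#' @return a nested list of class `run_config`.
#' @export
run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(
      image_shape = c(48L, 128L, 128L),
      n_centrioles = 36L, n_cilia = 31L, snr = 10,
      cilium_length_range_um = c(2, 6),
      count_table = list(n_animals = 2L, timepoints = c("1h", "6h"),
                         base_density_per_100um = 2.9,
                         drug_multiplier_subapical = 2.58,
                         length_um_range = c(900, 1150))),
    detection = list(scale_range_um = c(0.25, 0.5), n_scales = 3L,
                     threshold_policy = "otsu",
                     min_cilium_length_um = 2,
                     capture_radius_um = 0.5),
    grouping = list(linkage_cutoff_um = 2, min_group_size = 2L),
    tracking = list(gating_radius_um = 3, max_gap = 2L,
                    displacement_threshold_um = 0.5),
    stats = list(n_resamples = 10000L,
                 pair_on = c("animal_id", "timepoint", "compartment"))),
    class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults of [run_config()];
#' everything else keeps its default. The merged configuration is
#' validated before being returned.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param seed optional seed overriding both default and file.
#' @return a validated `run_config`.
#' @export
read_run_config <- function(path = NULL, seed = NULL) {
  cfg <- run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
    class(cfg) <- "run_config"
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  validate_run_config(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param config a `run_config`.
#' @return the config, invisibly; errors name the offending parameter.
#' @export
validate_run_config <- function(config) {
  if (config$grouping$linkage_cutoff_um <= 0)
    stop("config error: grouping$linkage_cutoff_um must be positive",
         call. = FALSE)
  if (config$tracking$gating_radius_um <= 0)
    stop("config error: tracking$gating_radius_um must be positive",
         call. = FALSE)
  if (config$detection$capture_radius_um <= 0)
    stop("config error: detection$capture_radius_um must be positive",
         call. = FALSE)
  if (config$stats$n_resamples < 100)
    stop("config error: stats$n_resamples must be >= 100", call. = FALSE)
  if (any(unlist(config$simulate$count_table$length_um_range) <= 0))
    stop("config error: simulate$count_table$length_um_range must be positive",
         call. = FALSE)
  invisible(config)
}

#' Run the pipeline end to end on synthetic data
#'
#' Generates a knob scene and a paired count table, runs spot and cilium
#' detection, association, grouping, and the paired permutation test, and
#' writes spots.csv, cilia.csv, groups.csv, counts.csv, result.json and
#' the serialized config (config.yaml) to `out_dir`.
#'
#' @param config a `run_config` (default: [run_config()]).
#' @param out_dir output directory, created if needed.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config = run_config(), out_dir = tempfile("run"),
                         quiet = FALSE) {
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage_seed <- function(stage) derive_seed(config$seed, stage)
  say("centriolr %s on R %s.%s; seed %d",
      as.character(utils::packageVersion("centriolr")),
      R.version$major, R.version$minor, config$seed)

  say("[simulate] knob scene (%d centrioles, %d cilia)",
      config$simulate$n_centrioles, config$simulate$n_cilia)
  sc <- scene_config(image_shape = config$simulate$image_shape,
                     snr = config$simulate$snr,
                     cilium_length_range_um =
                       unlist(config$simulate$cilium_length_range_um),
                     seed = stage_seed("simulate"))
  scene <- generate_knob_scene(sc, config$simulate$n_centrioles,
                               config$simulate$n_cilia)

  say("[detect] spots + cilia")
  spots <- detect_spots(scene$image,
                        scale_range_um = config$detection$scale_range_um,
                        n_scales = config$detection$n_scales)
  cilia <- detect_cilia(scene$image,
                        min_length_um = config$detection$min_cilium_length_um)
  assoc <- associate(spots, cilia,
                     capture_radius_um = config$detection$capture_radius_um)
  say("[detect] %d spots, %d cilia, fraction associated %.3f",
      nrow(spots), nrow(cilia), assoc$fraction_associated)

  say("[group] single-linkage clustering")
  grouping <- cluster_groups(spots,
                             linkage_cutoff_um =
                               config$grouping$linkage_cutoff_um,
                             min_group_size = config$grouping$min_group_size)

  say("[score] paired count table + permutation test")
  ct_cfg <- config$simulate$count_table
  counts <- generate_count_table(
    n_animals = ct_cfg$n_animals, timepoints = ct_cfg$timepoints,
    base_density_per_100um = ct_cfg$base_density_per_100um,
    drug_multiplier_by_compartment =
      list(subapical = ct_cfg$drug_multiplier_subapical),
    length_um_range = unlist(ct_cfg$length_um_range),
    seed = stage_seed("counts"))
  pairs <- pair_counts(counts, pair_on = config$stats$pair_on)
  test <- paired_permutation_test(pairs,
                                  n_resamples = config$stats$n_resamples,
                                  seed = stage_seed("test"))

  utils::write.csv(spots, file.path(out_dir, "spots.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(cilia), file.path(out_dir, "cilia.csv"),
                   row.names = FALSE)
  utils::write.csv(grouping$groups, file.path(out_dir, "groups.csv"),
                   row.names = FALSE)
  utils::write.csv(counts, file.path(out_dir, "counts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(statistic = test$statistic, observed_stat = test$observed_stat,
         p_value = test$p_value, n_pairs = test$n_pairs,
         mode = if (test$exact) "exact" else "monte-carlo",
         seed = config$seed,
         n_spots = nrow(spots), n_cilia = nrow(cilia),
         fraction_associated = assoc$fraction_associated),
    file.path(out_dir, "result.json"), auto_unbox = TRUE, digits = NA)
  yaml::write_yaml(unclass(config), file.path(out_dir, "config.yaml"))
  say("[done] outputs in %s", out_dir)
  invisible(list(scene = scene, spots = spots, cilia = cilia,
                 association = assoc, grouping = grouping, counts = counts,
                 test = test, out_dir = out_dir))
}
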