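#' Pipeline configuration
#'
#' Collects every tunable of the scene-to-traits pipeline with its default.
#' Unknown keys are rejected, so typos fail loudly.
#'
#' @param ... Overrides of: `voxel_size_mm` (0.1), `outlier_k` (20),
#'   `outlier_std_ratio` (2), `ransac_threshold_mm` (0.15),
#'   `ransac_iterations` (1000), `ransac_seed` (0), `rg_k` (30),
#'   `rg_angle_deg` (12), `rg_curvature` (1), `cluster_min` (200),
#'   `cluster_max` (20000), `n_slices` (9), `slice_interval_mm` (0.4),
#'   `slab_thickness_mm` (0.4), `circle_threshold_mm` (0.05),
#'   `circle_iterations` (500), `circle_seed` (0).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    voxel_size_mm = 0.1,
    outlier_k = 20,
    outlier_std_ratio = 2,
    ransac_threshold_mm = 0.15,
    ransac_iterations = 1000,
    ransac_seed = 0,
    rg_k = 30,
    rg_angle_deg = 12,
    rg_curvature = 1,
    cluster_min = 200,
    cluster_max = 20000,
    n_slices = 9,
    slice_interval_mm = 0.4,
    slab_thickness_mm = 0.4,
    circle_threshold_mm = 0.05,
    circle_iterations = 500,
    circle_seed = 0
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]])) {
    over <- over[[1]]
  }
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full scene-to-traits pipeline
#'
#' Reads (or takes) a merged stage scene, downsamples it, removes the stage
#' plane, denoises, segments single grains, and measures the 32 traits of
#' each. Outputs (when `output_dir` is given): `traits.csv`, one PLY per
#' grain, `report.json` with per-stage counts, and `config.json` echoing
#' the exact configuration used.
#'
#' @param input A point-cloud tibble or a path readable by
#'   [read_point_cloud()].
#' @param output_dir Optional output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param quiet Suppress progress messages.
#' @return A list: `traits` (tibble, one row per grain), `segments` (list of
#'   per-grain clouds), `report` (per-stage counts and warnings).
#' @export
run_pipeline <- function(input, output_dir = NULL, config = pipeline_config(),
                         quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  cloud <- if (is.character(input)) read_point_cloud(input) else as_tibble(input)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (nrow(cloud) == 0) abort("no points in the input cloud")
  validate_cloud(cloud)
  report <- list(n_input = nrow(cloud))
  say("input: %d points", nrow(cloud))

  cloud <- voxel_downsample(cloud, config$voxel_size_mm)
  report$n_downsampled <- nrow(cloud)
  say("downsampled (voxel %.2f mm): %d points", config$voxel_size_mm, nrow(cloud))

  plane <- fit_stage_plane(
    cloud,
    distance_threshold = config$ransac_threshold_mm,
    max_iterations = config$ransac_iterations,
    seed = config$ransac_seed
  )
  report$n_plane_inliers <- length(plane$inlier_indices)
  grains_cloud <- remove_stage(cloud, plane)
  report$n_above_stage <- nrow(grains_cloud)
  say("stage removed: %d plane inliers, %d points left",
      report$n_plane_inliers, nrow(grains_cloud))
  if (nrow(grains_cloud) <= config$outlier_k) {
    abort("no grains found: too few points remain after stage removal")
  }
  grains_cloud <- remove_outliers(grains_cloud, config$outlier_k,
                                  config$outlier_std_ratio)
  report$n_denoised <- nrow(grains_cloud)

  labelled <- segment_grains(
    grains_cloud,
    k_neighbors = config$rg_k,
    angle_threshold = config$rg_angle_deg,
    curvature_threshold = config$rg_curvature,
    min_cluster_size = config$cluster_min,
    max_cluster_size = config$cluster_max
  )
  segs <- split_segments(labelled, drop = integer(0))
  report$n_segments <- length(segs)
  say("segmentation: %d grains", length(segs))
  if (length(segs) == 0) abort("no grains found after segmentation")

  circle_args <- list(
    threshold = config$circle_threshold_mm,
    iterations = config$circle_iterations,
    seed = config$circle_seed
  )
  traits <- purrr::imap(segs, function(seg, id) {
    tryCatch(
      grain_traits(seg, id = as.integer(id), voxel_size = NULL,
                   n_slices = config$n_slices,
                   interval = config$slice_interval_mm,
                   slab_thickness = config$slab_thickness_mm,
                   circle_args = circle_args),
      error = function(e) {
        warn(sprintf("grain %s skipped: %s", id, conditionMessage(e)))
        NULL
      }
    )
  })
  traits <- dplyr::bind_rows(traits)
  report$n_measured <- nrow(traits)
  say("traits: %d grains x %d columns", nrow(traits), ncol(traits) - 1)
  if (nrow(traits) == 0) abort("no grains could be measured")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_trait_table(traits, file.path(output_dir, "traits.csv"))
    for (id in names(segs)) {
      write_point_cloud(segs[[id]],
                        file.path(output_dir, sprintf("grain_%s.ply", id)))
    }
    jsonlite::write_json(unclass(config),
                         file.path(output_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(report, file.path(output_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(traits = traits, segments = segs, report = report)
}

#' Run the L9 range analysis
#'
#' Reads an L9 design CSV (see [read_design_table()]) and performs the
#' Taguchi range analysis ([orthogonal_analysis()]); optionally writes the
#' result as JSON.
#'
#' @param design Path to the design CSV, or a design data frame.
#' @param output Optional JSON output path.
#' @param response Response column name (default: last column).
#' @return The `doe_analysis` object.
#' @export
run_doe <- function(design, output = NULL, response = NULL) {
  tab <- if (is.character(design)) read_design_table(design, response = response)
         else as_design_table(design, response = response)
  res <- orthogonal_analysis(tab)
  if (!is.null(output)) {
    jsonlite::write_json(
      list(
        K = as.data.frame(res$K),
        R = as.list(res$R),
        best_levels = as.list(res$best_levels),
        best_labels = as.list(res$best_labels)
      ),
      output, auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }
  res
}

#' Scatter plot of a (labelled) point cloud
#'
#' @param cloud A point-cloud tibble; a `label` column colours segments.
#' @param axes Which two coordinates to plot (default x, y).
#' @param point_size Point size.
#' @return A ggplot object.
#' @export
plot_cloud <- function(cloud, axes = c("x", "y"), point_size = 0.2) {
  validate_cloud(cloud)
  stopifnot(length(axes) == 2, all(axes %in% c("x", "y", "z")))
  df <- cloud
  gg <- ggplot2::ggplot(
    df, ggplot2::aes(x = .data[[axes[1]]], y = .data[[axes[2]]])
  )
  if ("label" %in% names(df)) {
    gg <- gg + ggplot2::geom_point(
      ggplot2::aes(colour = factor(.data$label)),
      size = point_size, show.legend = FALSE
    )
  } else {
    gg <- gg + ggplot2::geom_point(size = point_size, colour = "grey30")
  }
  gg + ggplot2::coord_equal() +
    ggplot2::labs(x = sprintf("%s (mm)", axes[1]), y = sprintf("%s (mm)", axes[2]))
}
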