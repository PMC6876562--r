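#' Pipeline configuration
#'
#' Bundles and validates every tunable of the end-to-end pipeline. Defaults
#' are the operating values for young olive orchards: 2 m terrain tiles,
#' lowest-15% ground rule, 0.3 m tree threshold, 0.1 m crown/voxel
#' resolution (the two are required to be equal — crown cells are the voxel
#' columns), 1 m seed radius, 3-cell noise filter.
#'
#' @param input Path to the input LAS (or CSV) point cloud.
#' @param output_dir Directory for all stage outputs (created if missing).
#' @param mode `"single_tree"` (each connected crown is one tree) or
#'   `"hedgerow"` (merged canopies are split between seed positions; needs
#'   `seeds` or `seeds_csv`).
#' @param seeds Optional seed table data frame (`tree_id`, `x`, `y`).
#' @param seeds_csv Optional path to a seed table CSV.
#' @param tile_size,ground_fraction DTM controls; see [build_dtm()].
#' @param tree_threshold Height threshold (m); see [classify_tree_points()].
#' @param cell_size,voxel_size Crown grid / voxel resolution (m); must be
#'   equal.
#' @param seed_radius Hedgerow assignment radius (m).
#' @param min_crown_cells Minimum crown size in cells.
#' @param crs Optional projected CRS identifier for the input.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(input, output_dir,
                            mode = c("single_tree", "hedgerow"),
                            seeds = NULL, seeds_csv = NULL,
                            tile_size = 2, ground_fraction = 0.15,
                            tree_threshold = 0.3,
                            cell_size = 0.1, voxel_size = 0.1,
                            seed_radius = 1, min_crown_cells = 3,
                            crs = NULL) {
  mode <- match.arg(mode)
  for (v in c(tile_size, ground_fraction, tree_threshold, cell_size,
              voxel_size, seed_radius))
    if (!is.numeric(v) || v <= 0)
      stop2("olivecloud_config", "all pipeline lengths must be > 0")
  if (abs(cell_size - voxel_size) > 1e-12)
    stop2("olivecloud_config",
          "cell_size and voxel_size must be equal: the crown grid is the ",
          "voxel column grid")
  if (mode == "hedgerow" && is.null(seeds) && is.null(seeds_csv))
    stop2("olivecloud_config",
          "hedgerow mode needs tree seed locations: pass seeds or seeds_csv ",
          "(or generate one from the planting pattern with generate_seed_grid)")
  if (!is.null(seeds_csv) && is.null(seeds)) seeds <- utils::read.csv(seeds_csv)
  if (!is.null(seeds)) check_seed_table(seeds)
  structure(list(input = input, output_dir = output_dir, mode = mode,
                 seeds = seeds, tile_size = tile_size,
                 ground_fraction = ground_fraction,
                 tree_threshold = tree_threshold, cell_size = cell_size,
                 voxel_size = voxel_size, seed_radius = seed_radius,
                 min_crown_cells = min_crown_cells, crs = crs),
            class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the [pipeline_config()] arguments; `overrides` (e.g. parsed
#' command-line flags) take precedence over file values.
#'
#' @param path YAML file path.
#' @param overrides Named list of values overriding the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  vals[names(overrides)] <- overrides
  do.call(pipeline_config, vals)
}

#' Run the full phenotyping pipeline
#'
#' Fully automatic, no user intervention: reads the cloud, builds the DTM,
#' normalizes heights, classifies tree points, delineates crowns (splitting
#' by seeds in hedgerow mode), voxelizes, and writes the per-tree trait
#' table plus all intermediate layers and a run manifest into `output_dir`:
#'
#' * `dtm.asc`, `dtm.csv` — terrain model raster and tile table
#' * `crowns.geojson`, `crown_labels.asc` — crown footprints and label raster
#' * `voxels.asc`, `voxels.csv` — per-column voxel counts, voxel indices
#' * `traits.csv` — the trait table ([characterize_trees()] columns)
#' * `manifest.json` — configuration echo, stage point/tree counts, versions
#'
#' Re-running with the same input and configuration reproduces the trait
#' table byte for byte. If a stage fails, outputs written so far are removed
#' and the error names the stage.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage progress messages?
#' @return Invisibly, a list with `dtm`, `crown_map`, `layer`, `records`,
#'   and the output paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$output_dir,
                     c(dtm_asc = "dtm.asc", dtm_csv = "dtm.csv",
                       crowns = "crowns.geojson",
                       labels_asc = "crown_labels.asc",
                       voxels_asc = "voxels.asc", voxels_csv = "voxels.csv",
                       traits = "traits.csv", manifest = "manifest.json"))
  names(paths) <- c("dtm_asc", "dtm_csv", "crowns", "labels_asc",
                    "voxels_asc", "voxels_csv", "traits", "manifest")
  say <- function(...) if (!quiet) message(...)
  t0 <- proc.time()[["elapsed"]]
  stage <- "read"
  res <- tryCatch({
    pc <- read_point_cloud(config$input, crs = config$crs)
    say(sprintf("[read] %d points from %s", n_points(pc), config$input))

    stage <- "dtm"
    dtm <- build_dtm(pc, config$tile_size, config$ground_fraction)
    write_dtm_asc(dtm, paths[["dtm_asc"]])
    write_dtm_csv(dtm, paths[["dtm_csv"]])
    say(sprintf("[dtm] %d x %d tiles (%d filled)",
                nrow(dtm$elevations), ncol(dtm$elevations),
                sum(dtm$fill_mask)))

    stage <- "normalize"
    pc <- normalize_heights(pc, dtm)

    stage <- "classify"
    tree_pc <- classify_tree_points(pc, config$tree_threshold)
    say(sprintf("[classify] %d tree points (threshold %.2f m)",
                n_points(tree_pc), config$tree_threshold))

    stage <- "delineate"
    occ <- rasterize_occupancy(tree_pc, config$cell_size)
    cm <- delineate_crowns(occ, config$min_crown_cells)
    if (config$mode == "hedgerow")
      cm <- assign_crowns_to_seeds(cm, config$seeds, config$seed_radius)
    say(sprintf("[delineate] %d crowns", n_crowns(cm)))
    write_ascii_grid(cm$labels, cm$origin, cm$cell_size,
                     paths[["labels_asc"]], na_value = -1)

    stage <- "voxelize"
    vox <- voxelize(tree_pc, config$voxel_size, origin = cm$origin)
    layer <- column_counts(vox, cm)
    write_voxel_layer_asc(layer, paths[["voxels_asc"]])
    write_voxels_csv(vox, paths[["voxels_csv"]])
    say(sprintf("[voxelize] %d occupied voxels", nrow(vox$idx)))

    stage <- "characterize"
    records <- characterize_trees(cm, layer, tree_pc)
    export_records(records, cm, paths[["crowns"]], paths[["traits"]])
    say(sprintf("[characterize] %d tree records", nrow(records)))

    stage <- "manifest"
    manifest <- list(
      package = "olivecloud",
      version = as.character(utils::packageVersion("olivecloud")),
      r_version = R.version.string,
      config = config[setdiff(names(config), "seeds")],
      n_seeds = if (is.null(config$seeds)) 0L else nrow(config$seeds),
      n_input_points = n_points(pc), n_tree_points = n_points(tree_pc),
      n_trees = nrow(records),
      elapsed_s = round(proc.time()[["elapsed"]] - t0, 2))
    jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                         digits = NA, null = "null")
    list(dtm = dtm, crown_map = cm, layer = layer, records = records,
         paths = as.list(paths))
  }, error = function(e) {
    unlink(paths)
    stop2("olivecloud_stage",
          "pipeline failed at stage '", stage, "': ", conditionMessage(e))
  })
  invisible(res)
}
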