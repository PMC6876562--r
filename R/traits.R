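#' Maximum tree height
#'
#' Height of a tree is the maximum normalized point height over its crown —
#' point heights, not voxel tops, so the estimate is not discretized twice.
#'
#' @param tree_pc A [point_cloud()] of the tree's points, either already
#'   normalized (`h` present) or accompanied by `dtm`.
#' @param dtm Optional `dtm_grid` used to normalize when `h` is absent.
#' @return Height above terrain (m).
#' @export
tree_height <- function(tree_pc, dtm = NULL) {
  stopifnot(inherits(tree_pc, "point_cloud"))
  if (is.null(tree_pc$h)) {
    if (is.null(dtm))
      stop2("olivecloud_state", "need normalized heights or a dtm")
    tree_pc <- normalize_heights(tree_pc, dtm)
  }
  if (length(tree_pc$h) == 0L)
    stop2("olivecloud_lookup", "no points for this tree")
  max(tree_pc$h)
}

#' Crown length and width from crown cells
#'
#' Length is the maximum distance between any two cell centers of the crown
#' plus one cell size (extent correction: centers under-span the cells they
#' represent by half a cell at each end); width is the extent of the centers
#' projected perpendicular to the length axis, plus one cell size. For a
#' single cell both equal the cell size. Guarantees `width <= length`.
#'
#' @param cells Data frame (or matrix) of crown cell centers with columns
#'   `x`, `y`, e.g. from [crown_cells()].
#' @param cell_size Cell side (m), default 0.1.
#' @return Named numeric vector `c(length =, width =)` in m.
#' @export
#' @examples
#' row10 <- data.frame(x = (1:10 - 0.5) * 0.1, y = 0.05)
#' crown_extents(row10)  # length 1.0, width 0.1
crown_extents <- function(cells, cell_size = 0.1) {
  cells <- as.data.frame(cells)
  if (nrow(cells) == 0L)
    stop2("olivecloud_invalid", "need at least one crown cell")
  if (nrow(cells) == 1L)
    return(c(length = cell_size, width = cell_size))
  pts <- unique(cells[, c("x", "y")])
  if (nrow(pts) == 1L)
    return(c(length = cell_size, width = cell_size))
  hull <- pts[grDevices::chull(pts$x, pts$y), , drop = FALSE]
  d2 <- outer(hull$x, hull$x, "-")^2 + outer(hull$y, hull$y, "-")^2
  far <- which(d2 == max(d2), arr.ind = TRUE)[1, ]
  len_span <- sqrt(max(d2))
  u <- c(hull$x[far[2]] - hull$x[far[1]], hull$y[far[2]] - hull$y[far[1]]) /
       len_span
  perp <- c(-u[2], u[1])
  proj <- hull$x * perp[1] + hull$y * perp[2]
  wid_span <- diff(range(proj))
  len <- len_span + cell_size
  wid <- min(wid_span + cell_size, len)
  c(length = len, width = wid)
}

#' Per-tree architectural trait records
#'
#' Combines the crown map, the voxel layer and the normalized tree cloud
#' into one record per tree: location (crown-cell centroid), maximum height,
#' crown length and width, projected area (`n_cells * cell_size^2`),
#' voxel-based crown volume, and cell/point counts. Records are ordered by
#' tree id.
#'
#' @param crown_map A `crown_map` (after seed assignment, in hedgerow mode).
#' @param layer The matching `voxel_layer` from [column_counts()].
#' @param tree_pc The normalized tree [point_cloud()].
#' @param dtm Optional `dtm_grid`, used only if `tree_pc` lacks heights.
#' @return Data frame of class `tree_records` with columns `tree_id`, `x`,
#'   `y`, `height_m`, `length_m`, `width_m`, `area_m2`, `volume_m3`,
#'   `n_cells`, `n_points`.
#' @export
characterize_trees <- function(crown_map, layer, tree_pc, dtm = NULL) {
  stopifnot(inherits(crown_map, "crown_map"), inherits(layer, "voxel_layer"))
  if (any(abs(layer$origin - crown_map$origin) > 1e-9) ||
      abs(layer$cell_size - crown_map$cell_size) > 1e-9 ||
      !identical(dim(layer$counts), dim(crown_map$labels)))
    stop2("olivecloud_alignment", "crown map and voxel layer do not align")
  stopifnot(inherits(tree_pc, "point_cloud"))
  if (is.null(tree_pc$h)) {
    if (is.null(dtm))
      stop2("olivecloud_state", "tree cloud lacks heights and no dtm given")
    tree_pc <- normalize_heights(tree_pc, dtm)
  }

  lab <- crown_map$labels
  cs <- crown_map$cell_size
  # label of the cell each point falls in (0 if outside the grid or crowns)
  pi_ <- as.integer(floor((tree_pc$x - crown_map$origin[1]) / cs)) + 1L
  pj <- as.integer(floor((tree_pc$y - crown_map$origin[2]) / cs)) + 1L
  inside <- pi_ >= 1L & pi_ <= nrow(lab) & pj >= 1L & pj <= ncol(lab)
  plab <- integer(length(pi_))
  plab[inside] <- lab[cbind(pi_[inside], pj[inside])]

  ids <- crown_map$ids
  recs <- lapply(ids, function(id) {
    cells <- crown_cells(crown_map, id)
    ext <- crown_extents(cells, cs)
    pts <- which(plab == id)
    height <- if (length(pts) > 0) max(tree_pc$h[pts])
              else max(layer$counts[lab == id]) * layer$voxel_size
    data.frame(tree_id = id,
               x = mean(cells$x), y = mean(cells$y),
               height_m = height,
               length_m = ext[["length"]], width_m = ext[["width"]],
               area_m2 = nrow(cells) * cs^2,
               volume_m3 = crown_volume(layer, id),
               n_cells = nrow(cells), n_points = length(pts))
  })
  out <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  if (is.null(out)) out <- data.frame(tree_id = integer(), x = double(),
                                      y = double(), height_m = double(),
                                      length_m = double(), width_m = double(),
                                      area_m2 = double(), volume_m3 = double(),
                                      n_cells = integer(), n_points = integer())
  class(out) <- c("tree_records", "data.frame")
  out
}

#' Export tree records as table and vector files
#'
#' Writes the trait table as CSV (stable columns: `tree_id, x, y, height_m,
#' length_m, width_m, area_m2, volume_m3, n_cells, n_points`) and the crown
#' footprints as a GeoJSON FeatureCollection (one MultiPolygon of crown
#' cells per tree, traits as properties).
#'
#' @param records A `tree_records` data frame from [characterize_trees()].
#' @param crown_map The `crown_map` the records were derived from (supplies
#'   the polygon geometry).
#' @param vector_path Output GeoJSON path (skipped if `NULL`).
#' @param table_path Output CSV path (skipped if `NULL`).
#' @return Invisibly, the paths written.
#' @export
export_records <- function(records, crown_map, vector_path, table_path) {
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop2("olivecloud_invalid", "records must be a non-empty data frame")
  written <- character()
  if (!is.null(table_path)) {
    utils::write.csv(as.data.frame(records), table_path, row.names = FALSE)
    written <- c(written, table_path)
  }
  if (!is.null(vector_path)) {
    stopifnot(inherits(crown_map, "crown_map"))
    feats <- lapply(seq_len(nrow(records)), function(r) {
      id <- records$tree_id[r]
      cells <- crown_cells(crown_map, id)
      h <- crown_map$cell_size / 2
      polys <- lapply(seq_len(nrow(cells)), function(i) {
        x <- cells$x[i]; y <- cells$y[i]
        list(list(
          c(x - h, y - h), c(x + h, y - h), c(x + h, y + h),
          c(x - h, y + h), c(x - h, y - h)))
      })
      list(type = "Feature",
           geometry = list(type = "MultiPolygon", coordinates = polys),
           properties = as.list(records[r, , drop = FALSE]))
    })
    fc <- list(type = "FeatureCollection", features = feats)
    jsonlite::write_json(fc, vector_path, auto_unbox = TRUE, digits = NA)
    written <- c(written, vector_path)
  }
  invisible(written)
}
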