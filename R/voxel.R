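#' Voxelize the tree point cloud
#'
#' Slices the normalized tree cloud into a regular 3D grid of cubic voxels
#' (default 0.1 m side, the resolution recommended for crown volume work on
#' small trees), anchored horizontally at the crown grid origin and
#' vertically at terrain level (`k = 0` is the slice 0 to `voxel_size` above
#' ground). A voxel is occupied iff at least one point falls in it; multiple
#' points in a voxel count once, so repeated photogrammetric sampling of the
#' same canopy spot does not inflate volume. Points with negative normalized
#' height are excluded (they cannot index a slice below the terrain).
#'
#' @param tree_pc A [point_cloud()] with normalized heights (`h`).
#' @param voxel_size Voxel side (m), default 0.1.
#' @param origin `(x, y)` grid anchor; defaults to floor-aligned cloud
#'   minimum. Use the crown map's origin so columns line up with crown cells.
#' @return A `voxel_set`: list with `origin`, `voxel_size` and `idx`, a
#'   data.table of unique occupied `(i, j, k)` indices (1-based `i`, `j`;
#'   `k >= 0`).
#' @export
voxelize <- function(tree_pc, voxel_size = 0.1, origin = NULL) {
  stopifnot(inherits(tree_pc, "point_cloud"))
  if (is.null(tree_pc$h))
    stop2("olivecloud_state",
          "cloud has no height_above_terrain; run normalize_heights() first")
  if (voxel_size <= 0) stop2("olivecloud_domain", "voxel_size must be > 0")
  keep <- tree_pc$h >= 0
  x <- tree_pc$x[keep]; y <- tree_pc$y[keep]; h <- tree_pc$h[keep]
  if (length(x) == 0L) {
    return(structure(list(origin = origin %||% c(0, 0),
                          voxel_size = voxel_size,
                          idx = data.table::data.table(i = integer(),
                                                       j = integer(),
                                                       k = integer())),
                     class = "voxel_set"))
  }
  if (is.null(origin))
    origin <- c(floor(min(x) / voxel_size) * voxel_size,
                floor(min(y) / voxel_size) * voxel_size)
  dt <- data.table::data.table(
    i = as.integer(floor((x - origin[1]) / voxel_size)) + 1L,
    j = as.integer(floor((y - origin[2]) / voxel_size)) + 1L,
    k = as.integer(floor(h / voxel_size)))
  if (any(dt$i < 1L) || any(dt$j < 1L))
    stop2("olivecloud_extent", "voxel origin lies above the cloud minimum")
  idx <- unique(dt)
  data.table::setkeyv(idx, c("i", "j", "k"))
  structure(list(origin = origin, voxel_size = voxel_size, idx = idx),
            class = "voxel_set")
}

#' @export
print.voxel_set <- function(x, ...) {
  cat(sprintf("<voxel_set> %d occupied voxels of %.2g m\n",
              nrow(x$idx), x$voxel_size))
  invisible(x)
}

#' Per-column occupied-voxel counts
#'
#' Builds the "Voxels" layer: a raster at the crown-grid resolution where
#' each crown cell stores the number of occupied voxels in its vertical
#' column (gaps between occupied slices do not count). Interior crown cells
#' (point-free pockets filled by [delineate_crowns()]) have no voxels of
#' their own; they receive the half-up-rounded mean count of their
#' point-bearing 8-neighbor crown cells, a conservative fill for canopy the
#' camera could not see inside (0 if no such neighbor). Cells outside any
#' crown are 0.
#'
#' @param vox A `voxel_set` sharing origin and cell size with `crown_map`.
#' @param crown_map A `crown_map` from [delineate_crowns()] (optionally
#'   after [assign_crowns_to_seeds()]).
#' @return A `voxel_layer`: list with the grid geometry, `counts` (integer
#'   matrix), `labels` (copy of the crown labels) and `voxel_size`.
#' @export
column_counts <- function(vox, crown_map) {
  stopifnot(inherits(vox, "voxel_set"), inherits(crown_map, "crown_map"))
  if (any(abs(vox$origin - crown_map$origin) > 1e-9) ||
      abs(vox$voxel_size - crown_map$cell_size) > 1e-9)
    stop2("olivecloud_alignment",
          "voxel set and crown map must share origin and cell size")
  lab <- crown_map$labels
  counts <- matrix(0L, nrow(lab), ncol(lab))
  if (nrow(vox$idx) > 0) {
    tab <- vox$idx[, list(n = .N), by = c("i", "j")]
    ok <- tab$i <= nrow(lab) & tab$j <= ncol(lab)
    tab <- tab[ok]
    sel <- cbind(tab$i, tab$j)
    inside <- lab[sel] > 0L & !crown_map$interior_mask[sel]
    counts[sel[inside, , drop = FALSE]] <- tab$n[inside]
  }
  # neighbor-mean fill of interior (point-free, enclosed) columns
  int_idx <- which(crown_map$interior_mask, arr.ind = TRUE)
  if (nrow(int_idx) > 0) {
    offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
    filled <- integer(nrow(int_idx))
    for (r in seq_len(nrow(int_idx))) {
      i <- int_idx[r, 1]; j <- int_idx[r, 2]
      ri <- int_idx[r, 1] + offs[, 1]
      rj <- int_idx[r, 2] + offs[, 2]
      ok <- ri >= 1 & ri <= nrow(lab) & rj >= 1 & rj <= ncol(lab)
      nb <- cbind(ri[ok], rj[ok])
      use <- lab[nb] > 0L & !crown_map$interior_mask[nb] & counts[nb] > 0L
      filled[r] <- if (any(use)) round_half_up(mean(counts[nb[use, , drop = FALSE]]))
                   else 0L
    }
    counts[int_idx] <- as.integer(filled)
  }
  structure(list(origin = crown_map$origin, cell_size = crown_map$cell_size,
                 voxel_size = vox$voxel_size, counts = counts, labels = lab,
                 interior_mask = crown_map$interior_mask),
            class = "voxel_layer")
}

#' @export
print.voxel_layer <- function(x, ...) {
  cat(sprintf("<voxel_layer> %d x %d cells; %d occupied columns; max count %d\n",
              nrow(x$counts), ncol(x$counts), sum(x$counts > 0),
              if (length(x$counts)) max(x$counts) else 0L))
  invisible(x)
}

#' Voxel-based crown volume of one tree
#'
#' Crown volume is the sum of the column counts over the tree's crown cells
#' times the voxel volume (`voxel_size^3`, i.e. 0.001 m^3 at the 0.1 m
#' default).
#'
#' @param layer A `voxel_layer` from [column_counts()].
#' @param tree_id A tree id present in the layer's labels.
#' @return Volume in m^3.
#' @export
crown_volume <- function(layer, tree_id) {
  stopifnot(inherits(layer, "voxel_layer"))
  if (!tree_id %in% layer$labels)
    stop2("olivecloud_lookup", "unknown tree_id: ", tree_id)
  sum(layer$counts[layer$labels == tree_id]) * layer$voxel_size^3
}

#' Export the voxel layer
#'
#' Writes the per-column counts as an ESRI ASCII grid and/or CSV; occupied
#' voxel indices can be dumped with `write_voxels_csv()` for debugging.
#'
#' @param layer A `voxel_layer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_voxel_layer_asc <- function(layer, path) {
  stopifnot(inherits(layer, "voxel_layer"))
  write_ascii_grid(layer$counts, layer$origin, layer$cell_size, path,
                   na_value = -1)
}

#' @rdname write_voxel_layer_asc
#' @param vox A `voxel_set`.
#' @export
write_voxels_csv <- function(vox, path) {
  stopifnot(inherits(vox, "voxel_set"))
  utils::write.csv(as.data.frame(vox$idx), path, row.names = FALSE)
  invisible(path)
}
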