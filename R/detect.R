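#' Classify tree points by height threshold
#'
#' Retains the points whose height above terrain is at least `threshold`
#' (inclusive). 0.3 m is the operating default for young olive orchards: tall
#' enough to reject ground and noise in fields without cover crops, low
#' enough to keep small trees. Requires normalized heights — run
#' [normalize_heights()] first.
#'
#' @param pc A [point_cloud()] with normalized heights.
#' @param threshold Height threshold (m), default 0.3.
#' @return A `point_cloud` containing only tree points (possibly empty).
#' @export
classify_tree_points <- function(pc, threshold = 0.3) {
  stopifnot(inherits(pc, "point_cloud"))
  if (is.null(pc$h))
    stop2("olivecloud_state",
          "cloud has no height_above_terrain; run normalize_heights() first")
  keep <- pc$h >= threshold
  point_cloud(pc$x[keep], pc$y[keep], pc$z[keep], h = pc$h[keep],
              crs = pc$crs)
}

#' Rasterize tree points to an occupancy grid
#'
#' Overlays a square grid (default 0.1 m cells) on the terrain and marks a
#' cell occupied iff at least one tree point projects into it (half-open
#' binning). The grid origin is floor-aligned to the cell size, like the DTM
#' tiling, so the grid does not depend on point order.
#'
#' @param tree_pc A [point_cloud()] of tree points (may be empty).
#' @param cell_size Cell side (m), default 0.1.
#' @param origin Optional `(x, y)` lower-left grid corner; defaults to the
#'   floor-aligned cloud minimum. Supply it to share geometry with a voxel
#'   grid built from the same cloud.
#' @return An `occupancy_grid`: list with `origin`, `cell_size`, `occupied`
#'   (logical matrix indexed `[ix, iy]`).
#' @export
rasterize_occupancy <- function(tree_pc, cell_size = 0.1, origin = NULL) {
  stopifnot(inherits(tree_pc, "point_cloud"))
  if (cell_size <= 0) stop2("olivecloud_domain", "cell_size must be > 0")
  if (length(tree_pc$x) == 0L) {
    return(structure(list(origin = origin %||% c(0, 0), cell_size = cell_size,
                          occupied = matrix(logical(), 0, 0)),
                     class = "occupancy_grid"))
  }
  if (is.null(origin))
    origin <- c(floor(min(tree_pc$x) / cell_size) * cell_size,
                floor(min(tree_pc$y) / cell_size) * cell_size)
  ix <- as.integer(floor((tree_pc$x - origin[1]) / cell_size)) + 1L
  iy <- as.integer(floor((tree_pc$y - origin[2]) / cell_size)) + 1L
  if (any(ix < 1L) || any(iy < 1L))
    stop2("olivecloud_extent", "grid origin lies above the cloud minimum")
  occ <- matrix(FALSE, max(ix), max(iy))
  occ[cbind(ix, iy)] <- TRUE
  structure(list(origin = origin, cell_size = cell_size, occupied = occ),
            class = "occupancy_grid")
}

#' Delineate individual tree crowns
#'
#' Merges occupied cells into crowns as 8-connected components (diagonal
#' adjacency counts, so sparse young crowns are not fragmented), numbered
#' 1..K in deterministic scan order. Components smaller than `min_cells`
#' cells are discarded as photogrammetric noise before anything else.
#' Point-free background pockets that are not connected to the grid border
#' are then filled into their enclosing crown — UAV photogrammetry rarely
#' sees the inside of a crown, so an enclosed hole is canopy, not ground —
#' and flagged in `interior_mask`.
#'
#' @param occ An `occupancy_grid` from [rasterize_occupancy()].
#' @param min_cells Minimum component size in cells (default 3, i.e.
#'   0.03 m^2 at 0.1 m cells); set to 1 to keep everything.
#' @return A `crown_map`: list with the grid geometry, `labels` (integer
#'   matrix, 0 = background), `interior_mask` (logical matrix), and `ids`.
#' @export
delineate_crowns <- function(occ, min_cells = 3) {
  stopifnot(inherits(occ, "occupancy_grid"))
  lab <- .label_components_cpp(occ$occupied, 8L)
  if (length(lab) > 0 && min_cells > 1 && max(lab) > 0) {
    sizes <- tabulate(lab, nbins = max(lab))
    drop <- which(sizes < min_cells)
    if (length(drop) > 0) {
      lab[lab %in% drop] <- 0L
      keep <- which(sizes >= min_cells)
      remap <- integer(max(lab, 1L))
      remap[keep] <- seq_along(keep)  # keep order = scan order
      lab[lab > 0L] <- remap[lab[lab > 0L]]
    }
  }
  interior <- matrix(FALSE, nrow(lab), ncol(lab))
  if (length(lab) > 0 && max(lab) > 0) {
    # Background connectivity is the complement of the 8-connected
    # foreground, hence 4-connected.
    bg <- .label_components_cpp(lab == 0L, 4L)
    if (max(bg) > 0) {
      border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
      enclosed <- setdiff(seq_len(max(bg)), c(0L, border))
      for (b in enclosed) {
        cells <- which(bg == b, arr.ind = TRUE)
        enc <- neighbor_values(lab, cells)
        enc <- enc[enc > 0L]
        if (length(enc) == 0L) next
        lab[cells] <- min(enc)
        interior[cells] <- TRUE
      }
    }
  }
  ids <- sort(unique(lab[lab > 0L]))
  structure(list(origin = occ$origin, cell_size = occ$cell_size,
                 labels = lab, interior_mask = interior, ids = ids),
            class = "crown_map")
}

# values of m in the 8-neighborhood of the given cells (arr.ind matrix)
neighbor_values <- function(m, cells) {
  offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  out <- integer(0)
  for (k in seq_len(nrow(offs))) {
    r <- cells[, 1] + offs[k, 1]
    c <- cells[, 2] + offs[k, 2]
    ok <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
    out <- c(out, m[cbind(r[ok], c[ok])])
  }
  out
}

#' @export
print.crown_map <- function(x, ...) {
  cat(sprintf("<crown_map> %d x %d cells of %.2g m; %d crowns; %d interior cells\n",
              nrow(x$labels), ncol(x$labels), x$cell_size,
              length(x$ids), sum(x$interior_mask)))
  invisible(x)
}

#' Number of delineated crowns
#' @param crown_map A `crown_map`.
#' @return Integer count of distinct tree labels.
#' @export
n_crowns <- function(crown_map) {
  stopifnot(inherits(crown_map, "crown_map"))
  length(crown_map$ids)
}

#' Cell centers of a crown map
#' @param crown_map A `crown_map`.
#' @param id Optional tree id; default all labeled cells.
#' @return Data frame with `x`, `y`, `label`, `interior`.
#' @export
crown_cells <- function(crown_map, id = NULL) {
  stopifnot(inherits(crown_map, "crown_map"))
  sel <- if (is.null(id)) crown_map$labels > 0L else crown_map$labels == id
  idx <- which(sel, arr.ind = TRUE)
  data.frame(
    x = crown_map$origin[1] + (idx[, 1] - 0.5) * crown_map$cell_size,
    y = crown_map$origin[2] + (idx[, 2] - 0.5) * crown_map$cell_size,
    label = crown_map$labels[idx],
    interior = crown_map$interior_mask[idx])
}

#' Assign crown cells to known tree positions (hedgerow mode)
#'
#' In super-high-density hedgerows, adjacent canopies touch and merge into a
#' single connected component. Given the known position of every tree (from
#' an earlier campaign or from the planting pattern), each labeled cell whose
#' center lies within `radius` of at least one seed is relabeled to the
#' *nearest* seed's tree id (ties to the lower id), which splits a merged
#' hedgerow component between its trees. Cells beyond every seed's radius
#' keep their component in a label namespace disjoint from the seed ids
#' (offset by the maximum seed id) and are listed in the `unassigned`
#' attribute. The operation is idempotent and independent of seed order.
#'
#' @param crown_map A `crown_map`.
#' @param seeds A seed table: data frame with unique `tree_id` and `x`, `y`
#'   positions (m).
#' @param radius Assignment radius (m); default 1, chosen from the planting
#'   distance between hedgerow trees.
#' @return A `crown_map` whose labels are seed tree ids (plus offset labels
#'   for unassigned components), with attribute `unassigned`.
#' @export
assign_crowns_to_seeds <- function(crown_map, seeds, radius = 1) {
  stopifnot(inherits(crown_map, "crown_map"))
  check_seed_table(seeds)
  lab <- crown_map$labels
  idx <- which(lab > 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(crown_map)
  cx <- crown_map$origin[1] + (idx[, 1] - 0.5) * crown_map$cell_size
  cy <- crown_map$origin[2] + (idx[, 2] - 0.5) * crown_map$cell_size

  ord <- order(seeds$tree_id)
  best_d2 <- rep(Inf, nrow(idx))
  best_id <- rep(NA_integer_, nrow(idx))
  for (s in ord) {
    d2 <- (cx - seeds$x[s])^2 + (cy - seeds$y[s])^2
    hit <- d2 < best_d2 - 1e-12   # strict: earlier (lower) id wins ties
    best_d2[hit] <- d2[hit]
    best_id[hit] <- seeds$tree_id[s]
  }
  within <- best_d2 <= radius^2 + 1e-12
  offset <- max(seeds$tree_id)
  new_lab <- ifelse(within, best_id, offset + lab[idx])
  out <- crown_map
  out$labels[idx] <- as.integer(new_lab)
  out$ids <- sort(unique(out$labels[out$labels > 0L]))
  attr(out, "unassigned") <- sort(unique(new_lab[!within]))
  out
}

check_seed_table <- function(seeds) {
  if (!is.data.frame(seeds) || nrow(seeds) == 0L ||
      !all(c("tree_id", "x", "y") %in% names(seeds)))
    stop2("olivecloud_invalid",
          "seeds must be a non-empty data frame with tree_id, x, y")
  if (anyDuplicated(seeds$tree_id))
    stop2("olivecloud_invalid", "duplicate seed tree_id values")
  invisible(seeds)
}

#' Generate a regular planting-pattern seed grid
#'
#' Builds the seed table for [assign_crowns_to_seeds()] from the planting
#' pattern when no earlier-campaign tree locations are available: `n_rows`
#' rows separated by `row_vector`, with `n_trees_per_row` trees spaced
#' `tree_spacing` apart along each row (the row runs perpendicular to
#' `row_vector`). Tree ids are sequential, row by row.
#'
#' @param origin `(x, y)` of the first tree (m).
#' @param row_vector `(dx, dy)` offset from one row to the next (m).
#' @param tree_spacing Distance between trees within a row (m).
#' @param n_rows,n_trees_per_row Pattern dimensions.
#' @return Seed table data frame (`tree_id`, `x`, `y`).
#' @export
#' @examples
#' generate_seed_grid(c(0, 0), c(0, 5), 1.75, n_rows = 1, n_trees_per_row = 3)
generate_seed_grid <- function(origin, row_vector, tree_spacing,
                               n_rows, n_trees_per_row) {
  if (tree_spacing <= 0) stop2("olivecloud_domain", "tree_spacing must be > 0")
  rlen <- sqrt(sum(row_vector^2))
  if (n_rows > 1 && rlen <= 0)
    stop2("olivecloud_domain", "row_vector must be non-zero for several rows")
  u <- if (rlen > 0) row_vector / rlen else c(0, 1)
  along <- c(u[2], -u[1])  # within-row direction, perpendicular to row_vector
  grid <- expand.grid(tree = seq_len(n_trees_per_row) - 1L,
                      row = seq_len(n_rows) - 1L)
  data.frame(
    tree_id = seq_len(nrow(grid)),
    x = origin[1] + grid$row * row_vector[1] + grid$tree * tree_spacing * along[1],
    y = origin[2] + grid$row * row_vector[2] + grid$tree * tree_spacing * along[2])
}

#' Tree counting accuracy
#'
#' Detected trees as a percentage of the visually observed (planted) trees.
#'
#' @param detected Number of trees found by the pipeline.
#' @param observed Number of trees actually present (> 0).
#' @param digits Rounding applied for reporting; default 1 decimal. Use
#'   `NULL` for the raw value.
#' @return Percentage.
#' @export
#' @examples
#' counting_accuracy(764, 806)  # 94.8
counting_accuracy <- function(detected, observed, digits = 1) {
  if (!is.numeric(observed) || any(observed <= 0))
    stop2("olivecloud_domain", "observed count must be > 0")
  if (!is.numeric(detected) || any(detected < 0))
    stop2("olivecloud_domain", "detected count must be >= 0")
  acc <- detected / observed * 100
  if (is.null(digits)) acc else round(acc, digits)
}
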