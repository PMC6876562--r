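#' Ground elevation of one terrain tile
#'
#' The terrain elevation assigned to a tile is the mean of its lowest points:
#' with `n` points in the tile, the `k = ceiling(fraction * n)` smallest
#' elevations are averaged (`k >= 1`). Taking only the lowest fraction
#' discards canopy returns so that tiles containing trees still estimate the
#' ground, provided enough ground is visible in the tile.
#'
#' @param z Numeric vector of point elevations (m) falling in the tile.
#' @param fraction Fraction of lowest points averaged; default 0.15.
#' @return Ground elevation estimate (m).
#' @export
#' @examples
#' tile_ground_elevation(0:9)           # k = ceiling(1.5) = 2 -> 0.5
#' tile_ground_elevation(rep(5, 8))     # 5
tile_ground_elevation <- function(z, fraction = 0.15) {
  if (length(z) == 0L)
    stop2("olivecloud_empty_tile", "empty tile: no points to estimate ground")
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop2("olivecloud_domain", "fraction must be in (0, 1]")
  k <- max(1L, as.integer(ceiling(fraction * length(z))))
  mean(sort(z, partial = k)[seq_len(k)])
}

#' Build a digital terrain model by chessboard tiling
#'
#' Partitions the cloud into square tiles (chessboard segmentation, default
#' 2 m side, sized to the planting pattern so every tile sees bare ground
#' between trees) and assigns each tile the [tile_ground_elevation()] of its
#' points. The grid origin is anchored at
#' `(floor(xmin/tile)*tile, floor(ymin/tile)*tile)` so the tiling does not
#' depend on point order. Tiles that received no points are filled from the
#' nearest non-empty tile center (ties broken toward the lowest elevation)
#' and flagged in `fill_mask`.
#'
#' @param pc A non-empty [point_cloud()].
#' @param tile_size Tile side (m); default 2.
#' @param fraction Lowest-points fraction passed to [tile_ground_elevation()].
#' @return A `dtm_grid`: list with `origin` (x, y of the lower-left corner),
#'   `tile_size`, `elevations` (matrix indexed `[ix, iy]`), and `fill_mask`
#'   (logical matrix, `TRUE` where interpolated).
#' @export
build_dtm <- function(pc, tile_size = 2, fraction = 0.15) {
  stopifnot(inherits(pc, "point_cloud"))
  if (length(pc$x) == 0L)
    stop2("olivecloud_invalid", "cannot build a DTM from an empty cloud")
  if (tile_size <= 0) stop2("olivecloud_domain", "tile_size must be > 0")

  x0 <- floor(min(pc$x) / tile_size) * tile_size
  y0 <- floor(min(pc$y) / tile_size) * tile_size
  ix <- as.integer(floor((pc$x - x0) / tile_size)) + 1L
  iy <- as.integer(floor((pc$y - y0) / tile_size)) + 1L
  nx <- max(ix); ny <- max(iy)

  dt <- data.table::data.table(ix = ix, iy = iy, z = pc$z)
  agg <- dt[, list(elev = tile_ground_elevation(z, fraction)),
            by = c("ix", "iy")]

  elev <- matrix(NA_real_, nx, ny)
  elev[cbind(agg$ix, agg$iy)] <- agg$elev
  fill <- is.na(elev)

  if (any(fill)) {
    half <- tile_size / 2
    emp <- which(fill, arr.ind = TRUE)
    nonemp <- which(!fill, arr.ind = TRUE)
    ne_x <- x0 + (nonemp[, 1] - 0.5) * tile_size
    ne_y <- y0 + (nonemp[, 2] - 0.5) * tile_size
    ne_z <- elev[nonemp]
    for (r in seq_len(nrow(emp))) {
      cx <- x0 + (emp[r, 1] - 0.5) * tile_size
      cy <- y0 + (emp[r, 2] - 0.5) * tile_size
      d2 <- (ne_x - cx)^2 + (ne_y - cy)^2
      cand <- which(d2 <= min(d2) + 1e-12)
      elev[emp[r, 1], emp[r, 2]] <- min(ne_z[cand])
    }
  }

  structure(list(origin = c(x0, y0), tile_size = tile_size,
                 elevations = elev, fill_mask = fill),
            class = "dtm_grid")
}

#' @export
print.dtm_grid <- function(x, ...) {
  cat(sprintf("<dtm_grid> %d x %d tiles of %.2g m; origin (%.2f, %.2f); %d filled\n",
              nrow(x$elevations), ncol(x$elevations), x$tile_size,
              x$origin[1], x$origin[2], sum(x$fill_mask)))
  cat(sprintf("  elevation range [%.3f, %.3f] m\n",
              min(x$elevations), max(x$elevations)))
  invisible(x)
}

#' Terrain elevation under given positions
#'
#' Piecewise-constant lookup: each position takes the elevation of the tile
#' containing it (half-open tile membership).
#'
#' @param dtm A `dtm_grid` from [build_dtm()].
#' @param x,y Numeric position vectors (m).
#' @return Elevations (m); `NA` for positions outside the grid.
#' @export
terrain_elevation <- function(dtm, x, y) {
  stopifnot(inherits(dtm, "dtm_grid"))
  ix <- as.integer(floor((x - dtm$origin[1]) / dtm$tile_size)) + 1L
  iy <- as.integer(floor((y - dtm$origin[2]) / dtm$tile_size)) + 1L
  out <- rep(NA_real_, length(x))
  ok <- ix >= 1L & ix <= nrow(dtm$elevations) &
        iy >= 1L & iy <= ncol(dtm$elevations)
  out[ok] <- dtm$elevations[cbind(ix[ok], iy[ok])]
  out
}

#' Normalize point heights against the terrain
#'
#' Computes each point's height above the terrain (`z` minus the elevation of
#' the DTM tile beneath it) and stores it in the cloud's `h` field. Slightly
#' negative values (noise below the estimated ground) are retained; they are
#' only excluded later, at tree-point classification and voxelization.
#'
#' @param pc A [point_cloud()].
#' @param dtm A `dtm_grid` covering the cloud's extent.
#' @return The cloud with `h` set.
#' @export
normalize_heights <- function(pc, dtm) {
  stopifnot(inherits(pc, "point_cloud"), inherits(dtm, "dtm_grid"))
  elev <- terrain_elevation(dtm, pc$x, pc$y)
  bad <- which(is.na(elev))
  if (length(bad) > 0)
    stop2("olivecloud_extent",
          "point ", bad[1], " at (", format(pc$x[bad[1]]), ", ",
          format(pc$y[bad[1]]), ") lies outside the DTM extent")
  point_cloud(pc$x, pc$y, pc$z, h = pc$z - elev, crs = pc$crs)
}

#' Compare a DTM against reference elevations
#'
#' Looks up the DTM elevation at each reference sample (typically a regular
#' validation grid, e.g. 20 m spacing, over the field) and regresses the DTM
#' estimates on the reference values. The returned RMSE is measured about the
#' fitted line, so a constant vertical bias between the two models shows up
#' in the intercept, not in the RMSE; set `rmse_about = "identity"` for
#' residuals about the 1:1 line instead. Samples can be excluded (e.g. known
#' anomalies in the reference product) via `exclude`.
#'
#' @param dtm A `dtm_grid`.
#' @param reference_samples Data frame with columns `x`, `y`, `elevation` (m).
#' @param exclude Optional logical vector flagging anomalous samples to drop.
#' @param rmse_about `"fit"` (default) or `"identity"`.
#' @return A `regression_stats` object (see [regression_stats()]).
#' @export
compare_dtm <- function(dtm, reference_samples, exclude = NULL,
                        rmse_about = "fit") {
  stopifnot(inherits(dtm, "dtm_grid"))
  s <- reference_samples
  if (!all(c("x", "y", "elevation") %in% names(s)))
    stop2("olivecloud_invalid",
          "reference_samples needs x, y, elevation columns")
  if (!is.null(exclude)) s <- s[!exclude, , drop = FALSE]
  est <- terrain_elevation(dtm, s$x, s$y)
  ok <- !is.na(est)
  if (sum(ok) < 3L)
    stop2("olivecloud_insufficient",
          "fewer than 3 usable reference samples within the DTM extent")
  regression_stats(observed = s$elevation[ok], estimated = est[ok],
                   rmse_about = rmse_about)
}

#' Export rasters and DTM tables
#'
#' `write_ascii_grid()` writes an ESRI ASCII grid (`.asc`), a plain-text
#' raster interchange format readable by standard GIS software.
#' `write_dtm_csv()` writes one row per tile with indices, center
#' coordinates, elevation and the interpolation flag.
#'
#' @param m Numeric matrix indexed `[ix, iy]` with `iy` increasing northward.
#' @param origin Lower-left corner `(x, y)` of the grid (m).
#' @param cell_size Cell side (m).
#' @param path Output path.
#' @param na_value NODATA value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(m, origin, cell_size, path, na_value = -9999) {
  nx <- nrow(m); ny <- ncol(m)
  hdr <- c(paste("ncols", nx), paste("nrows", ny),
           paste("xllcorner", format(origin[1], scientific = FALSE)),
           paste("yllcorner", format(origin[2], scientific = FALSE)),
           paste("cellsize", format(cell_size, scientific = FALSE)),
           paste("NODATA_value", na_value))
  m[is.na(m)] <- na_value
  rows <- vapply(rev(seq_len(ny)),
                 function(iy) paste(format(m[, iy], trim = TRUE),
                                    collapse = " "),
                 character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param dtm A `dtm_grid`.
#' @export
write_dtm_csv <- function(dtm, path) {
  stopifnot(inherits(dtm, "dtm_grid"))
  idx <- which(!is.na(dtm$elevations) | is.na(dtm$elevations), arr.ind = TRUE)
  d <- data.frame(
    i = idx[, 1], j = idx[, 2],
    x_center = dtm$origin[1] + (idx[, 1] - 0.5) * dtm$tile_size,
    y_center = dtm$origin[2] + (idx[, 2] - 0.5) * dtm$tile_size,
    elevation = dtm$elevations[idx],
    filled = dtm$fill_mask[idx])
  d <- d[order(d$j, d$i), ]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param dtm A `dtm_grid`.
#' @export
write_dtm_asc <- function(dtm, path) {
  stopifnot(inherits(dtm, "dtm_grid"))
  write_ascii_grid(dtm$elevations, dtm$origin, dtm$tile_size, path)
}
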