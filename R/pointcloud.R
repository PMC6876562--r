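#' Point cloud objects
#'
#' A `point_cloud` is the pipeline's sole input: a set of 3D points in a
#' projected (metric) coordinate system, where `z` is elevation above sea
#' level. After [normalize_heights()] each point additionally carries its
#' height above the terrain (`h`), which every downstream stage (tree point
#' classification, voxelization, trait extraction) works on.
#'
#' @param x,y,z Numeric vectors of equal length; planar coordinates and
#'   elevation, in meters. All values must be finite.
#' @param h Optional numeric vector of per-point heights above terrain (m),
#'   normally produced by [normalize_heights()] rather than supplied directly.
#' @param crs Optional projected-CRS identifier (e.g. `"EPSG:25830"`).
#'   Geographic (latitude/longitude) systems are rejected: all binning and
#'   distances assume metric coordinates.
#'
#' @return An object of class `point_cloud`: a list with elements `x`, `y`,
#'   `z`, optional `h`, and `crs`.
#' @seealso [read_point_cloud()], [crop()], [point_density()]
#' @export
#' @examples
#' pc <- point_cloud(c(0, 1, 0), c(0, 0, 1), c(10, 11, 10.5))
#' n_points(pc)
point_cloud <- function(x, y, z, h = NULL, crs = NULL) {
  x <- as.double(x); y <- as.double(y); z <- as.double(z)
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop2("olivecloud_invalid", "x, y, z must have equal length")
  if (n > 0 && (!all(is.finite(x)) || !all(is.finite(y)) || !all(is.finite(z))))
    stop2("olivecloud_invalid", "point coordinates must all be finite")
  if (!is.null(h)) {
    h <- as.double(h)
    if (length(h) != n)
      stop2("olivecloud_invalid",
            "height_above_terrain must have exactly one value per point")
  }
  if (!is.null(crs)) check_projected_crs(crs)
  structure(list(x = x, y = y, z = z, h = h, crs = crs),
            class = "point_cloud")
}

# Geographic CRS rejection. Full geodetic metadata handling is out of scope;
# we recognise the common geographic identifiers and anything self-describing
# as lat/lon, and accept the rest as projected.
check_projected_crs <- function(crs) {
  stopifnot(is.character(crs), length(crs) == 1L)
  geographic_epsg <- c("4326", "4258", "4267", "4269", "4230", "4023")
  code <- sub("^(EPSG|epsg):", "", crs)
  if (code %in% geographic_epsg || grepl("longlat|latlong|geographic", crs,
                                         ignore.case = TRUE))
    stop2("olivecloud_unit_error",
          "CRS '", crs, "' is geographic (lat/lon); ",
          "a projected metric CRS is required")
  invisible(crs)
}

#' @export
print.point_cloud <- function(x, ...) {
  cat(sprintf("<point_cloud> %d points", length(x$x)))
  if (length(x$x) > 0) {
    b <- bbox(x)
    cat(sprintf("; extent x [%.2f, %.2f] y [%.2f, %.2f] z [%.2f, %.2f]",
                b$xmin, b$xmax, b$ymin, b$ymax, min(x$z), max(x$z)))
  }
  cat(if (is.null(x$h)) "; heights: absolute\n" else "; heights: normalized\n")
  if (!is.null(x$crs)) cat("  crs:", x$crs, "\n")
  invisible(x)
}

#' @export
as.data.frame.point_cloud <- function(x, ...) {
  d <- data.frame(x = x$x, y = x$y, z = x$z)
  if (!is.null(x$h)) d$h <- x$h
  d
}

#' Number of points in a point cloud
#' @param pc A [point_cloud()].
#' @return Integer count.
#' @export
n_points <- function(pc) {
  stopifnot(inherits(pc, "point_cloud"))
  length(pc$x)
}

#' Axis-aligned bounding boxes
#'
#' @param xmin,ymin,xmax,ymax Box limits in meters; `xmin < xmax`,
#'   `ymin < ymax`.
#' @return An object of class `bounding_box`.
#' @export
#' @examples
#' bounding_box(0, 0, 10, 5)
bounding_box <- function(xmin, ymin, xmax, ymax) {
  if (!all(is.finite(c(xmin, ymin, xmax, ymax))))
    stop2("olivecloud_invalid", "bounding box limits must be finite")
  if (xmin >= xmax || ymin >= ymax)
    stop2("olivecloud_invalid", "bounding box requires xmin < xmax, ymin < ymax")
  structure(list(xmin = xmin, ymin = ymin, xmax = xmax, ymax = ymax),
            class = "bounding_box")
}

#' @rdname bounding_box
#' @param pc A non-empty [point_cloud()] whose extent is returned. The box is
#'   widened by a hair above the max so that every point satisfies the
#'   half-open `[min, max)` membership rule used throughout the package.
#' @export
bbox <- function(pc) {
  stopifnot(inherits(pc, "point_cloud"))
  if (length(pc$x) == 0)
    stop2("olivecloud_invalid", "cannot take the bounding box of an empty cloud")
  eps <- 1e-9
  bounding_box(min(pc$x), min(pc$y),
               max(pc$x) + max(eps, abs(max(pc$x)) * eps),
               max(pc$y) + max(eps, abs(max(pc$y)) * eps))
}

#' Point density
#'
#' Number of points per square meter over a given area, the standard summary
#' of photogrammetric cloud quality (field campaigns of this kind report
#' roughly 4,000-5,000 points/m^2).
#'
#' @param pc A [point_cloud()].
#' @param area Either a positive area in m^2 or a [bounding_box()].
#' @return Points per m^2.
#' @export
#' @examples
#' pc <- point_cloud(runif(100, 0, 5), runif(100, 0, 5), rep(0, 100))
#' point_density(pc, 25)  # 4.0
point_density <- function(pc, area) {
  stopifnot(inherits(pc, "point_cloud"))
  if (inherits(area, "bounding_box"))
    area <- (area$xmax - area$xmin) * (area$ymax - area$ymin)
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area <= 0)
    stop2("olivecloud_domain", "area must be a single positive number")
  length(pc$x) / area
}

#' Crop a point cloud to a bounding box
#'
#' Retains exactly the points with `xmin <= x < xmax` and `ymin <= y < ymax`
#' (half-open, the binning convention used by every grid in the package, so
#' no point can be counted by two adjacent boxes).
#'
#' @param pc A [point_cloud()].
#' @param box A [bounding_box()].
#' @return A `point_cloud` with the retained points (possibly empty).
#' @export
crop <- function(pc, box) {
  stopifnot(inherits(pc, "point_cloud"), inherits(box, "bounding_box"))
  keep <- pc$x >= box$xmin & pc$x < box$xmax &
          pc$y >= box$ymin & pc$y < box$ymax
  point_cloud(pc$x[keep], pc$y[keep], pc$z[keep],
              h = if (!is.null(pc$h)) pc$h[keep], crs = pc$crs)
}
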