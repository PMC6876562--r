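#' Synthetic orchard specification
#'
#' Describes a synthetic young-olive orchard with known ground truth, used
#' to exercise every pipeline stage without real UAV data. Defaults emulate
#' the second-campaign (27 months after planting) field conditions of the
#' trials the pipeline was designed around: an intensive discontinuous
#' planting at 7 x 5 m (286 trees/ha) or a super-high-density hedgerow at
#' 1.75 x 5 m (1143 trees/ha), flat drip-irrigated ground, photogrammetric
#' clouds of roughly 4,500 points/m^2, RTK-grade vertical noise, tree
#' heights of 1-3 m and crown diameters of 1.2-2.2 m (hedgerow canopies
#' begin to touch at the 1.75 m spacing at this age).
#'
#' Canopy points are surface-biased by default (`surface_bias = 1`):
#' photogrammetric reconstruction sees the crown envelope, rarely the
#' inside. The crown sits on a trunk with its base at `crown_base` above
#' ground, so a healthy young tree's canopy lies entirely above the 0.3 m
#' classification threshold; set `trunk_points = TRUE` to also emit trunk
#' points below the threshold and exercise its rejection behavior.
#'
#' @param training_system `"intensive"` or `"hedgerow"`; sets the default
#'   spacings and pattern dimensions.
#' @param tree_spacing,row_spacing Planting pattern (m).
#' @param n_rows,n_trees_per_row Pattern dimensions (defaults: intensive
#'   4 x 5 = 20 trees; hedgerow 3 x 20 = 60 trees).
#' @param terrain `"flat"`, or a list `list(type = "sloped", gradient = g)`
#'   (rise per meter along x) or `list(type = "undulating", amplitude = a,
#'   wavelength = w)`.
#' @param ground_density,canopy_density Points per m^2 of ground surface /
#'   of projected crown area.
#' @param min_points_per_tree Floor on canopy points per tree, so small
#'   crowns are still well sampled.
#' @param noise_sigma Gaussian z-noise standard deviation (m).
#' @param crown_shape `"cone"` or `"ellipsoid"`.
#' @param height_range,crown_diameter_range Uniform sampling ranges (m) for
#'   per-tree total height and widest crown diameter (the second diameter is
#'   drawn within 85-100% of the first).
#' @param crown_base Height of the crown base above ground (m).
#' @param surface_bias Fraction of canopy points on the crown envelope (the
#'   rest are uniform in the crown interior).
#' @param trunk_points Emit trunk points below the crown base?
#' @param margin Bare-ground margin around the planting grid (m).
#' @param seed Integer RNG seed; same seed, same orchard, byte for byte.
#' @return An `orchard_spec` list.
#' @export
orchard_spec <- function(training_system = c("intensive", "hedgerow"),
                         tree_spacing = NULL, row_spacing = 5,
                         n_rows = NULL, n_trees_per_row = NULL,
                         terrain = "flat",
                         ground_density = 4500, canopy_density = 4500,
                         min_points_per_tree = 3000,
                         noise_sigma = 0.02,
                         crown_shape = c("cone", "ellipsoid"),
                         height_range = c(1, 3),
                         crown_diameter_range = c(1.2, 2.2),
                         crown_base = 0.4,
                         surface_bias = 1,
                         trunk_points = FALSE,
                         margin = 2, seed = 1L) {
  training_system <- match.arg(training_system)
  crown_shape <- match.arg(crown_shape)
  if (is.null(tree_spacing))
    tree_spacing <- if (training_system == "intensive") 7 else 1.75
  if (is.null(n_rows))
    n_rows <- if (training_system == "intensive") 4L else 3L
  if (is.null(n_trees_per_row))
    n_trees_per_row <- if (training_system == "intensive") 5L else 20L
  if (tree_spacing <= 0 || row_spacing <= 0)
    stop2("olivecloud_domain", "spacings must be > 0")
  if (ground_density <= 0 || canopy_density <= 0)
    stop2("olivecloud_domain", "densities must be > 0")
  if (height_range[1] < 0.3)
    stop2("olivecloud_domain",
          "height_range minimum must be >= 0.3 m (the tree-point threshold)")
  if (is.character(terrain)) terrain <- list(type = terrain)
  if (!terrain$type %in% c("flat", "sloped", "undulating"))
    stop2("olivecloud_domain", "unknown terrain type: ", terrain$type)
  structure(list(training_system = training_system,
                 tree_spacing = tree_spacing, row_spacing = row_spacing,
                 n_rows = as.integer(n_rows),
                 n_trees_per_row = as.integer(n_trees_per_row),
                 terrain = terrain,
                 ground_density = ground_density,
                 canopy_density = canopy_density,
                 min_points_per_tree = min_points_per_tree,
                 noise_sigma = noise_sigma, crown_shape = crown_shape,
                 height_range = height_range,
                 crown_diameter_range = crown_diameter_range,
                 crown_base = crown_base, surface_bias = surface_bias,
                 trunk_points = trunk_points, margin = margin,
                 seed = as.integer(seed)),
            class = "orchard_spec")
}

orchard_extent <- function(spec) {
  list(xmax = (spec$n_trees_per_row - 1) * spec$tree_spacing + 2 * spec$margin,
       ymax = (spec$n_rows - 1) * spec$row_spacing + 2 * spec$margin)
}

terrain_fun <- function(terrain) {
  switch(terrain$type,
         flat = function(x, y) rep(0, length(x)),
         sloped = function(x, y) terrain$gradient * x,
         undulating = function(x, y)
           terrain$amplitude * sin(2 * pi * x / terrain$wavelength))
}

# terrain points without touching the RNG seed (callers seed once)
sample_terrain <- function(spec) {
  ext <- orchard_extent(spec)
  f <- terrain_fun(spec$terrain)
  n <- stats::rpois(1, spec$ground_density * ext$xmax * ext$ymax)
  x <- runif(n, 0, ext$xmax)
  y <- runif(n, 0, ext$ymax)
  z <- f(x, y) + rnorm(n, 0, spec$noise_sigma)
  list(x = x, y = y, z = z, f = f)
}

#' Sample synthetic terrain
#'
#' Ground returns for the orchard footprint: a Poisson-distributed number of
#' uniformly placed points at `ground_density`, with Gaussian vertical noise
#' `noise_sigma` about the analytic terrain surface. Deterministic given
#' `spec$seed`.
#'
#' @param spec An [orchard_spec()].
#' @return List with the ground [point_cloud()] (`cloud`) and the analytic
#'   terrain function `f(x, y)` (`terrain_fn`).
#' @export
make_terrain <- function(spec) {
  stopifnot(inherits(spec, "orchard_spec"))
  set.seed(spec$seed)
  g <- sample_terrain(spec)
  list(cloud = point_cloud(g$x, g$y, g$z), terrain_fn = g$f)
}

#' Sample a synthetic tree crown
#'
#' Canopy points in the tree's own frame (crown base at z = 0, apex at
#' z = `height`): a cone or ellipsoid with horizontal semi-axes `d1/2` and
#' `d2/2`. With `surface_bias = 1` all points lie on the crown envelope —
#' what photogrammetry reconstructs — with the sampling uniform per unit of
#' projected area, so the apex is naturally thin: the expected number of
#' points within the top 0.1 m of a cone is `n * (0.1 / height)^2`, i.e.
#' well-sampled apexes need on the order of `(height / 0.1)^2` points.
#' Interior points (fraction `1 - surface_bias`) are uniform in the solid.
#'
#' @param shape `"cone"` or `"ellipsoid"`.
#' @param height Crown height (m), > 0.
#' @param d1,d2 Crown diameters (m), > 0.
#' @param n Number of points.
#' @param surface_bias Fraction of points on the envelope.
#' @return Data frame with `x`, `y`, `z` in the tree frame.
#' @export
make_tree <- function(shape, height, d1, d2, n, surface_bias = 1) {
  if (height <= 0 || d1 <= 0 || d2 <= 0)
    stop2("olivecloud_domain", "height and diameters must be > 0")
  n <- as.integer(n)
  on_surface <- runif(n) < surface_bias
  theta <- runif(n, 0, 2 * pi)
  if (shape == "cone") {
    # t: normalized height in [0, 1]; radius shrinks linearly to the apex
    t <- ifelse(on_surface, 1 - sqrt(runif(n)), 1 - runif(n)^(1 / 3))
    s <- ifelse(on_surface, 1, sqrt(runif(n)))  # radial factor inside
    data.frame(x = (1 - t) * s * (d1 / 2) * cos(theta),
               y = (1 - t) * s * (d2 / 2) * sin(theta),
               z = t * height)
  } else {
    # spheroid centered at height/2; surface points from normalized
    # Gaussians scaled to the axes (approximately area-uniform)
    g <- matrix(rnorm(3L * n), ncol = 3L)
    g <- g / sqrt(rowSums(g^2))
    rad <- ifelse(on_surface, 1, runif(n)^(1 / 3))
    data.frame(x = rad * g[, 1] * d1 / 2,
               y = rad * g[, 2] * d2 / 2,
               z = height / 2 + rad * g[, 3] * height / 2)
  }
}

#' Generate a synthetic orchard with ground truth
#'
#' Places one crown per planting position on the sampled terrain and returns
#' the merged point cloud together with an analytic ground-truth table and
#' the seed table of tree positions. Per-tree height and widest diameter are
#' drawn uniformly from the spec ranges (`d2` within 85-100% of `d1`); the
#' number of canopy points is `canopy_density` times the true projected area
#' with a floor of `min_points_per_tree`. Adjacent crowns wider than the
#' planting distance overlap (the hedgerow situation) and are flagged.
#' Deterministic given `spec$seed`.
#'
#' @param spec An [orchard_spec()].
#' @return List with `cloud` (the [point_cloud()]), `truth` (data frame:
#'   `tree_id`, `x`, `y`, `true_height_m`, `true_d1_m`, `true_d2_m`,
#'   `true_area_m2`, `true_volume_m3`, `n_canopy_points`, `overlaps`),
#'   `seeds` (seed table), and `terrain_fn`.
#' @export
#' @examples
#' orch <- make_orchard(orchard_spec("intensive", ground_density = 50,
#'                                   canopy_density = 200,
#'                                   min_points_per_tree = 200, seed = 7))
#' nrow(orch$truth)  # 20 trees
make_orchard <- function(spec) {
  stopifnot(inherits(spec, "orchard_spec"))
  set.seed(spec$seed)
  g <- sample_terrain(spec)

  seeds <- generate_seed_grid(c(spec$margin, spec$margin),
                              c(0, spec$row_spacing), spec$tree_spacing,
                              spec$n_rows, spec$n_trees_per_row)
  nt <- nrow(seeds)
  h_tot <- runif(nt, spec$height_range[1], spec$height_range[2])
  h_tot <- pmax(h_tot, spec$crown_base + 0.2)  # crown must exist above base
  d1 <- runif(nt, spec$crown_diameter_range[1], spec$crown_diameter_range[2])
  d2 <- d1 * runif(nt, 0.85, 1)
  area <- pi * d1 * d2 / 4
  n_pts <- pmax(as.integer(round(spec$canopy_density * area)),
                as.integer(spec$min_points_per_tree))

  parts <- vector("list", nt)
  for (t in seq_len(nt)) {
    crown <- make_tree(spec$crown_shape, h_tot[t] - spec$crown_base,
                       d1[t], d2[t], n_pts[t], spec$surface_bias)
    px <- seeds$x[t] + crown$x
    py <- seeds$y[t] + crown$y
    base <- g$f(px, py)
    pz <- base + spec$crown_base + crown$z + rnorm(n_pts[t], 0, spec$noise_sigma)
    if (spec$trunk_points) {
      nt_pts <- max(10L, as.integer(spec$crown_base / 0.05))
      tz <- runif(nt_pts, 0, spec$crown_base)
      px <- c(px, seeds$x[t] + rnorm(nt_pts, 0, 0.01))
      py <- c(py, seeds$y[t] + rnorm(nt_pts, 0, 0.01))
      pz <- c(pz, g$f(rep(seeds$x[t], nt_pts), rep(seeds$y[t], nt_pts)) + tz)
    }
    parts[[t]] <- list(x = px, y = py, z = pz)
  }

  cloud <- point_cloud(c(g$x, unlist(lapply(parts, `[[`, "x"))),
                       c(g$y, unlist(lapply(parts, `[[`, "y"))),
                       c(g$z, unlist(lapply(parts, `[[`, "z"))))

  # a crown overlaps when the planting distance to a neighbor is smaller
  # than the sum of the two half-diameters (checked against all trees)
  overlaps <- vapply(seq_len(nt), function(t) {
    dx <- seeds$x - seeds$x[t]; dy <- seeds$y - seeds$y[t]
    dist <- sqrt(dx^2 + dy^2)
    any(dist > 0 & dist < (d1 + d1[t]) / 2)
  }, logical(1))

  truth <- data.frame(tree_id = seeds$tree_id, x = seeds$x, y = seeds$y,
                      true_height_m = h_tot, true_d1_m = d1, true_d2_m = d2,
                      true_area_m2 = area,
                      true_volume_m3 = area * h_tot / 3,
                      n_canopy_points = n_pts, overlaps = overlaps)
  list(cloud = cloud, truth = truth, seeds = seeds, terrain_fn = g$f)
}
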