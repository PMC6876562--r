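test_that("tile ground elevation averages the lowest ceil(fraction*n) points", {
  # 17 points at 1.0 and 3 at 2.0: k = ceil(0.15*20) = 3, all lowest are 1.0
  expect_equal(tile_ground_elevation(c(rep(1, 17), rep(2, 3))), 1)
  expect_equal(tile_ground_elevation(rep(5, 8)), 5)
  # k = ceil(0.15*10) = 2 -> mean(0, 1)
  expect_equal(tile_ground_elevation(0:9), 0.5)
  expect_equal(tile_ground_elevation(3, 0.15), 3)  # k floored at 1
  expect_error(tile_ground_elevation(numeric(0)),
               class = "olivecloud_empty_tile")
  expect_error(tile_ground_elevation(1:3, fraction = 0),
               class = "olivecloud_domain")
})

test_that("tile rule is monotone and bounded by the mean", {
  set.seed(5)
  for (r in 1:50) {
    z <- rnorm(sample(1:40, 1), sd = 2)
    est <- tile_ground_elevation(z)
    expect_lte(est, mean(z))
    # adding a point below the estimate can only pull it down
    expect_lte(tile_ground_elevation(c(z, est - 1)), est)
  }
})

test_that("build_dtm recovers flat and analytic sloped terrain", {
  set.seed(7)
  n <- 5000
  x <- runif(n, 0, 20); y <- runif(n, 0, 10)
  flat <- point_cloud(x, y, rep(7, n))
  dtm <- build_dtm(flat)
  expect_true(all(abs(dtm$elevations - 7) < 1e-12))
  expect_false(any(dtm$fill_mask))

  # plane z = 2 + 0.01 x at 100 pts/m^2 within each 2 m tile
  z <- 2 + 0.01 * x
  dtm <- build_dtm(point_cloud(x, y, z))
  centers_x <- dtm$origin[1] + (seq_len(nrow(dtm$elevations)) - 0.5) * 2
  truth <- 2 + 0.01 * centers_x
  err <- sweep(dtm$elevations, 1, truth)
  expect_lte(sqrt(mean(err^2)), 0.05)
  # tiles cannot leave the z range of their source cloud
  expect_gte(min(dtm$elevations), min(z))
  expect_lte(max(dtm$elevations), max(z))
})

test_that("build_dtm is invariant to point order", {
  set.seed(9)
  n <- 1000
  pc <- point_cloud(runif(n, 0, 10), runif(n, 0, 10), rnorm(n, 5, 0.5))
  perm <- sample(n)
  pc2 <- point_cloud(pc$x[perm], pc$y[perm], pc$z[perm])
  expect_identical(build_dtm(pc)$elevations, build_dtm(pc2)$elevations)
})

test_that("empty tiles are filled from the nearest tile and flagged", {
  # two clusters 10 m apart leave empty tiles between them
  set.seed(3)
  x <- c(runif(200, 0, 2), runif(200, 12, 14))
  y <- runif(400, 0, 2)
  z <- c(rep(1, 200), rep(3, 200))
  dtm <- build_dtm(point_cloud(x, y, z))
  expect_true(any(dtm$fill_mask))
  expect_true(all(is.finite(dtm$elevations)))
  # tiles near the low cluster inherit its elevation
  expect_equal(terrain_elevation(dtm, 5, 1), 1)
  expect_equal(terrain_elevation(dtm, 11, 1), 3)
})

test_that("single-point cloud yields a one-tile DTM at that elevation", {
  dtm <- build_dtm(point_cloud(3.7, 1.1, 42))
  expect_equal(dim(dtm$elevations), c(1L, 1L))
  expect_equal(dtm$elevations[1, 1], 42)
})

test_that("normalize_heights subtracts the tile elevation and keeps negatives", {
  base <- point_cloud(runif(500, 0, 4), runif(500, 0, 4), rep(9.7, 500))
  dtm <- build_dtm(base)
  pc <- normalize_heights(point_cloud(1, 1, 10), dtm)
  expect_equal(pc$h, 0.3)
  below <- normalize_heights(point_cloud(1, 1, 9.5), dtm)
  expect_equal(below$h, -0.2)  # retained, not clipped
  expect_error(normalize_heights(point_cloud(50, 50, 10), dtm),
               class = "olivecloud_extent")
})

test_that("heights of on-terrain points are ~0 within DTM error", {
  set.seed(13)
  n <- 20000
  pc <- point_cloud(runif(n, 0, 20), runif(n, 0, 20),
                    rnorm(n, 100, 0.02))
  dtm <- build_dtm(pc)
  norm <- normalize_heights(pc, dtm)
  expect_lte(max(abs(mean(norm$h))), 0.1)
  expect_lte(sd(norm$h), 0.05)
})

test_that("compare_dtm reports perfect fits and constant offsets", {
  set.seed(21)
  pc <- point_cloud(runif(3000, 0, 20), runif(3000, 0, 20),
                    100 + 0.05 * runif(3000, 0, 20))
  pc <- point_cloud(pc$x, pc$y, 100 + 0.05 * pc$x)
  dtm <- build_dtm(pc)
  grid <- expand.grid(x = seq(1, 19, 2), y = seq(1, 19, 2))
  samples <- data.frame(grid, elevation = terrain_elevation(dtm, grid$x, grid$y))

  st <- compare_dtm(dtm, samples)
  expect_equal(st$r_squared, 1)
  expect_equal(st$rmse, 0, tolerance = 1e-12)

  # constant 0.5 m offset: R^2 unchanged, RMSE about the fit still 0,
  # the bias sits in the intercept
  off <- samples; off$elevation <- off$elevation + 0.5
  st2 <- compare_dtm(dtm, off)
  expect_equal(st2$r_squared, 1)
  expect_equal(st2$rmse, 0, tolerance = 1e-12)
  expect_equal(st2$intercept, -0.5, tolerance = 1e-9)
  expect_equal(st2$slope, 1, tolerance = 1e-9)
})

test_that("compare_dtm handles noisy reference samples and exclusions", {
  set.seed(28)
  n <- 40000
  x <- runif(n, 0, 60); y <- runif(n, 0, 20)
  relief <- function(x) x / 60  # 1 m of relief across the field
  pc <- point_cloud(x, y, 100 + relief(x) + rnorm(n, 0, 0.01))
  dtm <- build_dtm(pc)
  grid <- expand.grid(x = seq(2, 58, length.out = 7), y = seq(2, 18, 5))
  stopifnot(nrow(grid) == 28)
  samples <- data.frame(grid,
                        elevation = 100 + relief(grid$x) +
                          rnorm(nrow(grid), 0, 0.03))
  # attainable R^2 with sigma = 0.03 samples on ~1 m relief is about
  # 1 - sigma^2 / var(relief) ~ 0.989; assert a hair below it
  st <- compare_dtm(dtm, samples)
  expect_gte(st$r_squared, 0.98)

  # anomalous samples can be dismissed by mask
  bad <- samples; bad$elevation[1] <- 50
  st3 <- compare_dtm(dtm, bad, exclude = seq_len(nrow(bad)) == 1)
  expect_gte(st3$r_squared, 0.98)
  expect_error(compare_dtm(dtm, samples[1:2, ]),
               class = "olivecloud_insufficient")
})

test_that("DTM exports are readable text rasters and tables", {
  pc <- point_cloud(runif(400, 0, 4), runif(400, 0, 4), rep(2, 400))
  dtm <- build_dtm(pc)
  asc <- withr::local_tempfile(fileext = ".asc")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_dtm_asc(dtm, asc)
  write_dtm_csv(dtm, csv)
  lines <- readLines(asc)
  expect_match(lines[1], "^ncols 2$")
  expect_match(lines[5], "^cellsize 2$")
  tab <- read.csv(csv)
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$elevation == 2))
})
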