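test_that("tree point classification thresholds inclusively at 0.3 m", {
  pc <- point_cloud(1:3, 1:3, 1:3, h = c(0.29, 0.30, 0.31))
  kept <- classify_tree_points(pc)
  expect_equal(kept$h, c(0.30, 0.31))

  none <- classify_tree_points(point_cloud(1:3, 1:3, 1:3,
                                           h = c(0.1, 0.2, 0.29)))
  expect_equal(n_points(none), 0L)

  expect_error(classify_tree_points(point_cloud(1, 1, 1)),
               class = "olivecloud_state")
})

test_that("occupancy rasterization matches per-point binning", {
  one <- rasterize_occupancy(point_cloud(0.51, 0.52, 1, h = 1))
  expect_equal(sum(one$occupied), 1L)

  two <- rasterize_occupancy(point_cloud(c(0.51, 0.56), c(0.52, 0.53),
                                         c(1, 1), h = c(1, 1)))
  expect_equal(sum(two$occupied), 1L)  # 0.05 m apart, same 0.1 m cell

  set.seed(17)
  pc <- point_cloud(runif(1000, 0, 5), runif(1000, 0, 5), runif(1000),
                    h = runif(1000, 0.3, 2))
  occ <- rasterize_occupancy(pc)
  want <- bf_cells(pc$x, pc$y, occ$origin, occ$cell_size)
  got <- which(occ$occupied, arr.ind = TRUE)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got[, 1], got[, 2]),
                  paste(want$i, want$j))
})

test_that("crown delineation separates blobs, fills rings, keeps singletons", {
  # two blobs separated by an empty diagonal gap -> two crowns
  occ <- matrix(FALSE, 10, 10)
  occ[2:3, 2:3] <- TRUE
  occ[6:8, 6:8] <- TRUE
  om <- structure(list(origin = c(0, 0), cell_size = 0.1, occupied = occ),
                  class = "occupancy_grid")
  cm <- delineate_crowns(om, min_cells = 1)
  expect_equal(n_crowns(cm), 2L)
  expect_equal(cm$labels[2, 2], 1L)  # scan order: first-seen blob is 1

  # closed ring: one crown, interior filled and flagged
  ring <- matrix(FALSE, 9, 9)
  ring[3:7, 3:7] <- TRUE
  ring[4:6, 4:6] <- FALSE
  rm_ <- structure(list(origin = c(0, 0), cell_size = 0.1, occupied = ring),
                   class = "occupancy_grid")
  cmr <- delineate_crowns(rm_, min_cells = 1)
  expect_equal(n_crowns(cmr), 1L)
  expect_true(all(cmr$labels[4:6, 4:6] == 1L))
  expect_true(all(cmr$interior_mask[4:6, 4:6]))
  expect_equal(sum(cmr$interior_mask), 9L)

  # single occupied cell
  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  sm <- structure(list(origin = c(0, 0), cell_size = 0.1, occupied = single),
                  class = "occupancy_grid")
  cms <- delineate_crowns(sm, min_cells = 1)
  expect_equal(n_crowns(cms), 1L)
  expect_equal(sum(cms$interior_mask), 0L)
})

test_that("noise components below min_cells are discarded before filling", {
  occ <- matrix(FALSE, 10, 10)
  occ[2:4, 2:4] <- TRUE    # 9 cells, kept
  occ[8, 8] <- TRUE        # 1 cell, noise
  om <- structure(list(origin = c(0, 0), cell_size = 0.1, occupied = occ),
                  class = "occupancy_grid")
  cm <- delineate_crowns(om, min_cells = 3)
  expect_equal(n_crowns(cm), 1L)
  expect_equal(cm$labels[8, 8], 0L)
})

test_that("delineation agrees with a union-find oracle on random grids", {
  set.seed(23)
  for (r in 1:20) {
    occ <- random_grid(60, 60, runif(1, 0.1, 0.6))
    om <- structure(list(origin = c(0, 0), cell_size = 0.1, occupied = occ),
                    class = "occupancy_grid")
    cm <- delineate_crowns(om, min_cells = 1)
    # compare pre-fill partition: drop filled cells
    lab <- cm$labels
    lab[cm$interior_mask] <- 0L
    oracle <- uf_components(occ, 8)
    expect_equal(max(lab), oracle$n)
    expect_true(same_partition(lab, oracle$comp, occ))
  }
})

test_that("interior filling preserves label count and never fills border-connected cells", {
  set.seed(29)
  for (r in 1:10) {
    occ <- random_grid(40, 40, 0.45)
    om <- structure(list(origin = c(0, 0), cell_size = 0.1, occupied = occ),
                    class = "occupancy_grid")
    cm <- delineate_crowns(om, min_cells = 1)
    expect_equal(n_crowns(cm), uf_components(occ, 8)$n)
    # any background cell 4-connected to the border must stay background
    bg <- !occ
    reach <- matrix(FALSE, 40, 40)
    frontier <- which(bg & (row(bg) %in% c(1, 40) | col(bg) %in% c(1, 40)))
    reach[frontier] <- TRUE
    repeat {
      grown <- reach
      grown[-1, ] <- grown[-1, ] | reach[-40, ]
      grown[-40, ] <- grown[-40, ] | reach[-1, ]
      grown[, -1] <- grown[, -1] | reach[, -40]
      grown[, -40] <- grown[, -40] | reach[, -1]
      grown <- grown & bg
      if (identical(grown, reach)) break
      reach <- grown
    }
    expect_true(all(cm$labels[reach] == 0L))
    expect_true(all(cm$interior_mask[reach] == FALSE))
  }
})

test_that("seed assignment splits merged hedgerow components by nearest seed", {
  # a 20-cell occupied row spanning two seeds 1.75 m apart
  occ <- matrix(FALSE, 25, 3)
  occ[3:22, 2] <- TRUE
  om <- structure(list(origin = c(0, 0), cell_size = 0.1, occupied = occ),
                  class = "occupancy_grid")
  cm <- delineate_crowns(om, min_cells = 1)
  expect_equal(n_crowns(cm), 1L)
  seeds <- data.frame(tree_id = c(1L, 2L), x = c(0.5, 2.25), y = c(0.15, 0.15))
  out <- assign_crowns_to_seeds(cm, seeds, radius = 1)

  cells <- crown_cells(out)
  # brute-force nearest-seed assignment
  d1 <- sqrt((cells$x - 0.5)^2 + (cells$y - 0.15)^2)
  d2 <- sqrt((cells$x - 2.25)^2 + (cells$y - 0.15)^2)
  want <- ifelse(pmin(d1, d2) > 1, NA_integer_, ifelse(d1 <= d2, 1L, 2L))
  expect_equal(cells$label[!is.na(want)], want[!is.na(want)])
  expect_true(all(cells$label[is.na(want)] > 2L))  # disjoint namespace
})

test_that("seed assignment boundary, tie, idempotence and order invariance", {
  occ <- matrix(TRUE, 1, 1)
  om <- structure(list(origin = c(0, 0), cell_size = 0.1, occupied = occ),
                  class = "occupancy_grid")
  cm <- delineate_crowns(om, min_cells = 1)
  # cell center (0.05, 0.05); seed 0.9 m away -> assigned
  near <- data.frame(tree_id = 7L, x = 0.95, y = 0.05)
  expect_equal(assign_crowns_to_seeds(cm, near)$labels[1, 1], 7L)
  # seed 1.1 m away -> unassigned
  far <- data.frame(tree_id = 7L, x = 1.15, y = 0.05)
  out <- assign_crowns_to_seeds(cm, far)
  expect_gt(out$labels[1, 1], 7L)
  expect_length(attr(out, "unassigned"), 1L)
  # equidistant seeds: lower id wins
  tie <- data.frame(tree_id = c(9L, 4L), x = c(0.55, -0.45), y = c(0.05, 0.05))
  expect_equal(assign_crowns_to_seeds(cm, tie)$labels[1, 1], 4L)
  expect_equal(assign_crowns_to_seeds(cm, tie[2:1, ])$labels[1, 1], 4L)
  # idempotent
  once <- assign_crowns_to_seeds(cm, near)
  twice <- assign_crowns_to_seeds(once, near)
  expect_identical(once$labels, twice$labels)
  # duplicate ids rejected
  dup <- data.frame(tree_id = c(1L, 1L), x = c(0, 1), y = c(0, 0))
  expect_error(assign_crowns_to_seeds(cm, dup), class = "olivecloud_invalid")
})

test_that("seed grids follow the planting pattern", {
  g <- generate_seed_grid(c(0, 0), c(0, 5), 1.75, 1, 3)
  expect_equal(g$x, c(0, 1.75, 3.5))
  expect_equal(g$y, rep(0, 3))

  g2 <- generate_seed_grid(c(10, 20), c(0, 5), 7, 2, 2)
  expect_equal(nrow(g2), 4)
  expect_setequal(g2$x, c(10, 17))
  expect_setequal(g2$y, c(20, 25))

  hedge <- generate_seed_grid(c(0, 0), c(0, 5), 1.75, 3, 20)
  expect_equal(nrow(hedge), 60)
  d <- as.matrix(dist(hedge[, c("x", "y")]))
  diag(d) <- Inf
  expect_equal(min(d), 1.75)
})

test_that("counting accuracy reproduces the campaign detection rates", {
  counts <- olive_detection_counts()
  acc <- counting_accuracy(counts$detected_trees, counts$field_trees)
  expect_equal(acc, c(94.8, 93.4, 98.8, 100))
  expect_equal(counting_accuracy(0, 10), 0)
  expect_error(counting_accuracy(5, 0), class = "olivecloud_domain")
  expect_error(counting_accuracy(-1, 10), class = "olivecloud_domain")
})
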