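# Independent oracles used across tests. These deliberately avoid the
# package's production code paths: plain filters, per-point binning and a
# hand-written union-find.

bf_crop <- function(df, box) {
  df[df$x >= box$xmin & df$x < box$xmax &
     df$y >= box$ymin & df$y < box$ymax, , drop = FALSE]
}

bf_cells <- function(x, y, origin, cell) {
  unique(data.frame(i = floor((x - origin[1]) / cell) + 1,
                    j = floor((y - origin[2]) / cell) + 1))
}

bf_voxels <- function(x, y, h, origin, vs) {
  keep <- h >= 0
  unique(data.frame(i = floor((x[keep] - origin[1]) / vs) + 1,
                    j = floor((y[keep] - origin[2]) / vs) + 1,
                    k = floor(h[keep] / vs)))
}

# union-find component count over an occupancy matrix
uf_components <- function(occ, connectivity = 8) {
  nr <- nrow(occ); nc <- ncol(occ)
  id <- which(occ)
  if (length(id) == 0) return(list(n = 0L, comp = integer(0)))
  pos <- integer(nr * nc); pos[id] <- seq_along(id)
  parent <- seq_along(id)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  offs <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  rr <- (id - 1) %% nr + 1
  cc <- (id - 1) %/% nr + 1
  for (k in seq_len(nrow(offs))) {
    r2 <- rr + offs[k, 1]; c2 <- cc + offs[k, 2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= nc
    nb <- (c2[ok] - 1) * nr + r2[ok]
    src <- which(ok)[occ[nb]]
    nbp <- pos[nb[occ[nb]]]
    for (e in seq_along(src)) {
      a <- find(pos[id[src[e]]]); b <- find(nbp[e])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_along(id), find, integer(1))
  list(n = length(unique(roots)), comp = match(roots, unique(roots)))
}

# label maps describe the same partition of occupied cells
same_partition <- function(lab, comp_oracle, occ) {
  cells <- which(occ)
  a <- lab[cells]
  b <- comp_oracle
  length(unique(a)) == length(unique(b)) &&
    !anyDuplicated(unique(data.frame(a, b))[, 1]) &&
    !anyDuplicated(unique(data.frame(a, b))[, 2])
}

random_grid <- function(nr, nc, p) matrix(runif(nr * nc) < p, nr, nc)

# small, fast orchard spec for unit tests (full-density runs live in the
# acceptance suite)
tiny_spec <- function(training_system = "intensive", ...) {
  args <- utils::modifyList(list(training_system = training_system,
                                 ground_density = 150, canopy_density = 300,
                                 min_points_per_tree = 400), list(...))
  do.call(orchard_spec, args)
}

expect_pc_equal <- function(a, b, tol = 1e-9) {
  expect_equal(a$x, b$x, tolerance = tol)
  expect_equal(a$y, b$y, tolerance = tol)
  expect_equal(a$z, b$z, tolerance = tol)
}
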