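make_rod <- function(k, dims = c(max(k + 4L, 8L), 8L, 8L)) {
  g <- array(0L, dims)
  g[seq_len(k) + 2L, 4L, 4L] <- 1L
  voxel_model(g, 1)
}

test_that("voxel graphs match brute-force 26-adjacency", {
  rod <- make_rod(3L)
  vg <- build_voxel_graph(rod)
  expect_identical(igraph::vcount(vg$graph), 3)
  expect_identical(igraph::ecount(vg$graph), 2)
  expect_equal(sort(unique(igraph::E(vg$graph)$weight)), 1)

  g2 <- array(0L, c(8, 8, 8)); g2[3:4, 3:4, 3:4] <- 1L
  block <- voxel_model(g2, 1)
  vb <- build_voxel_graph(block)
  expect_identical(igraph::ecount(vb$graph), choose(8, 2))  # complete on 2x2x2

  # L-shaped solid: edge count equals an exhaustive pair scan
  gl <- array(0L, c(10, 10, 10))
  gl[3:7, 3:4, 3:4] <- 1L
  gl[3:4, 3:8, 3:4] <- 1L
  lshape <- voxel_model(gl, 1)
  idx <- which(lshape$grid == 1L, arr.ind = TRUE)
  d2 <- as.matrix(stats::dist(idx))^2
  oracle_edges <- sum(d2 > 0 & d2 <= 3 + 1e-9) / 2
  expect_identical(igraph::ecount(build_voxel_graph(lshape)$graph),
                   oracle_edges)
  expect_error(build_voxel_graph(voxel_model(array(0L, c(8, 8, 8)), 1)),
               "empty")
})

test_that("inner distances equal the Floyd-Warshall oracle on random solids", {
  for (seed in 1:10) {
    solid <- rand_solid(sample(c(60, 120, 200), 1L), seed = seed)
    b <- extract_boundary(solid)
    n <- min(15L, nrow(b$indices))
    s <- sample_random(b, n, seed = seed)
    D <- inner_distance_matrix(build_voxel_graph(solid), s)
    fw <- fw_distances(solid)
    rows <- fw_rows_of_samples(fw, s)
    expect_equal(unclass(D)[, ], fw$D[rows, rows], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("a straight one-voxel rod realises the unique path metric", {
  rod <- make_rod(7L, dims = c(12L, 8L, 8L))
  b <- extract_boundary(rod)
  s <- sample_uniform(b, nrow(b$indices), seed = 1)
  D <- inner_distance_matrix(build_voxel_graph(rod), s)
  expect_true(all(diag(D) == 0))
  expect_equal(max(D), 6)  # endpoints 6 steps apart at unit spacing
  # each pairwise distance is the index gap along the rod
  gap <- abs(outer(s$lattice[, 1L], s$lattice[, 1L], "-"))
  expect_equal(unclass(D)[, ], gap + 0, ignore_attr = TRUE)
})

test_that("inner distance dominates Euclidean and nearly meets it on a ball", {
  ball <- make_ball(10, 32)
  s <- sample_uniform(extract_boundary(ball), 60, seed = 2)
  Di <- inner_distance_matrix(build_voxel_graph(ball), s)
  De <- euclidean_distance_matrix(s)
  expect_true(all(Di - De >= -1e-9))
  # on a convex solid the 26-connected lattice metric overshoots the straight
  # line by a bounded factor (~8% in the continuum; finite resolution adds a
  # little)
  off <- upper.tri(Di)
  expect_lt(max(Di[off] / De[off]), 1.15)

  tube <- make_bent_tube(bend_angle = 240, dims = 32)
  st <- sample_uniform(extract_boundary(tube), 60, seed = 2)
  Dt <- inner_distance_matrix(build_voxel_graph(tube), st)
  Et <- euclidean_distance_matrix(st)
  expect_true(all(Dt - Et >= -1e-9))
  expect_gt(max(Dt / pmax(Et, 1e-12)), 1.5)  # genuinely non-convex
})

test_that("euclidean matrix matches independently computed pair norms", {
  s <- sample_random(extract_boundary(make_ball(6, 20)), 25, seed = 4)
  De <- euclidean_distance_matrix(s)
  oracle <- as.matrix(stats::dist(s$points))
  expect_equal(unclass(De)[, ], oracle, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(isSymmetric(unclass(De)[, ]))
  expect_identical(dist_kind(De), "euclidean")
})

test_that("samples split across components raise or reduce explicitly", {
  two <- voxelize_atoms(data.frame(x = c(0, 6), y = 0, z = 0, radius = 2), 32)
  b <- extract_boundary(two)
  s <- sample_random(b, 20, seed = 1)
  vg <- build_voxel_graph(two)
  expect_error(inner_distance_matrix(vg, s), "connected components")
  expect_warning(Dk <- inner_distance_matrix(vg, s, on_disconnected = "largest"),
                 "keeping the largest")
  kept <- attr(Dk, "kept")
  expect_true(length(kept) < 20 && length(kept) > 0)
  expect_true(all(is.finite(Dk)))
})

test_that("bending changes inner distances less than Euclidean ones", {
  straight <- make_bent_tube(bend_angle = 0, dims = 40)
  bent <- make_bent_tube(bend_angle = 240, dims = 40)
  tip_euclid <- function(m) {
    tips <- attr(m, "tips")
    sqrt(sum((tips[1L, ] - tips[2L, ])^2))
  }
  di <- c(tip_inner_distance(straight)$distance,
          tip_inner_distance(bent)$distance)
  de <- c(tip_euclid(straight), tip_euclid(bent))
  rel <- function(x) abs(x[2L] - x[1L]) / x[1L]
  expect_lt(rel(di), 0.25)
  expect_gt(rel(de), 0.5)
  expect_lt(rel(di), rel(de))
})

test_that("boundary-only graphs give the surface-geodesic variant", {
  ball <- make_ball(6, 20)
  s <- sample_uniform(extract_boundary(ball), 30, seed = 3)
  Dg <- inner_distance_matrix(build_voxel_graph(ball, boundary_only = TRUE), s)
  Di <- inner_distance_matrix(build_voxel_graph(ball), s)
  expect_identical(dist_kind(Dg), "geodesic")
  expect_true(all(Dg - Di >= -1e-9))  # surface paths cannot beat inner paths
})
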