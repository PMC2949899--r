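test_that("solid ball voxelization matches the analytic sphere volume", {
  b <- make_ball(10, 32)
  expect_lt(abs(n_object_voxels(b) - 4 / 3 * pi * 10^3) / (4 / 3 * pi * 10^3),
            0.05)
  # sub-voxel radius captures only the centre lattice point
  expect_identical(n_object_voxels(make_ball(0.6, 12)), 1L)
  # deterministic re-run
  expect_identical(make_ball(5, 16)$grid, make_ball(5, 16)$grid)
  expect_error(make_ball(20, 16), "radius too large")
})

test_that("mesh rasterization: sphere volume and exact cube counts", {
  sph <- icosphere(3, radius = 1)
  vm <- voxelize_mesh(sph, 32)
  analytic <- 4 / 3 * pi / vm$spacing^3
  expect_lt(abs(n_object_voxels(vm) - analytic) / analytic, 0.10)

  # axis-aligned unit cube: oracle is a brute-force point-in-cube test at
  # every lattice centre
  cv <- as.matrix(expand.grid(x = c(-.5, .5), y = c(-.5, .5), z = c(-.5, .5)))
  cf <- rbind(
    c(1, 3, 4), c(1, 4, 2), c(5, 6, 8), c(5, 8, 7),  # z faces
    c(1, 2, 6), c(1, 6, 5), c(3, 7, 8), c(3, 8, 4),  # y faces
    c(1, 5, 7), c(1, 7, 3), c(2, 4, 8), c(2, 8, 6)   # x faces
  )
  cube <- triangle_mesh(cv, cf)
  expect_true(isTRUE(mesh_is_watertight(cube)))
  vm2 <- voxelize_mesh(cube, 16)
  ax <- lapply(1:3, function(a) vm2$origin[a] + (seq_len(16) - 1) * vm2$spacing)
  oracle <- sum(outer(outer(abs(ax[[1]]) < 0.5, abs(ax[[2]]) < 0.5, "&"),
                      abs(ax[[3]]) < 0.5, "&"))
  expect_identical(n_object_voxels(vm2), as.integer(oracle))
  expect_identical(oracle, as.integer(14^3))  # cube spans dims - 2 per axis
})

test_that("non-watertight and degenerate meshes are rejected with a reason", {
  sph <- icosphere(1)
  open_mesh <- triangle_mesh(sph$vertices, sph$faces[-1L, ])
  expect_error(voxelize_mesh(open_mesh, 16), "not shared by exactly two")
  flat <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                        rbind(c(1, 2, 3), c(1, 3, 2)))
  expect_error(voxelize_mesh(flat, 16), "zero-volume|empty model")
})

test_that("boundary extraction finds exactly the 26-neighbourhood surface", {
  block <- function(k, dims = k + 4L) {
    g <- array(0L, rep(dims, 3L))
    i <- seq_len(k) + 2L
    g[i, i, i] <- 1L
    voxel_model(g, 1)
  }
  b3 <- extract_boundary(block(3L))
  expect_identical(nrow(b3$indices), 26L)  # all but the centre voxel
  expect_false(any(b3$indices[, 1L] == 4L & b3$indices[, 2L] == 4L &
                     b3$indices[, 3L] == 4L))
  expect_identical(nrow(extract_boundary(block(5L))$indices), 98L)  # 5^3 - 3^3
  expect_identical(nrow(extract_boundary(block(1L))$indices), 1L)
  # deterministic ordering on re-extraction
  expect_identical(b3$indices, extract_boundary(block(3L))$indices)
})

test_that("sphere-union rasterization has analytic volume and connectivity", {
  one <- voxelize_atoms(data.frame(x = 0, y = 0, z = 0, radius = 1), 24)
  analytic <- 4 / 3 * pi / one$spacing^3
  expect_lt(abs(n_object_voxels(one) - analytic) / analytic, 0.10)
  two_far <- voxelize_atoms(data.frame(x = c(0, 5), y = 0, z = 0, radius = 2), 32)
  expect_identical(n_components(two_far), 2L)
  two_near <- voxelize_atoms(data.frame(x = c(0, 2.5), y = 0, z = 0, radius = 2), 32)
  expect_identical(n_components(two_near), 1L)
  expect_error(voxelize_atoms(data.frame(x = numeric(), y = numeric(),
                                         z = numeric(), radius = numeric())),
               "empty atom list")
  expect_error(voxelize_atoms(data.frame(x = 0, y = 0, z = 0, radius = 0)),
               "radii")
})

test_that("model validation enforces binary occupancy and padding", {
  g <- array(0L, c(8, 8, 8)); g[4, 4, 4] <- 2L
  expect_error(voxel_model(g, 1), "0 or 1")
  g2 <- array(0L, c(8, 8, 8)); g2[1, 4, 4] <- 1L
  expect_error(voxel_model(g2, 1), "outermost")
  # every rasterizer honours the margin
  for (m in list(make_ball(5, 16),
                 voxelize_mesh(icosphere(2), 16),
                 voxelize_atoms(data.frame(x = 0, y = 0, z = 0, radius = 1), 16),
                 make_bent_tube(bend_angle = 200, dims = 24))) {
    d <- m$dims
    expect_identical(sum(m$grid[c(1, d[1]), , ]) + sum(m$grid[, c(1, d[2]), ]) +
                       sum(m$grid[, , c(1, d[3])]), 0L)
  }
})

test_that("quarter-turn rotations are voxel-exact and of order four", {
  tube <- make_bent_tube(bend_angle = 120, dims = 24)
  for (ax in c("x", "y", "z")) {
    r4 <- rotate_model_90(tube, ax, 4L)
    expect_identical(r4$grid, tube$grid)
    expect_identical(n_object_voxels(rotate_model_90(tube, ax, 1L)),
                     n_object_voxels(tube))
  }
})

test_that("voxel raster text format round-trips with its sidecar", {
  tube <- make_bent_tube(bend_angle = 60, dims = 16)
  path <- tempfile(fileext = ".vox")
  on.exit(unlink(c(path, paste0(path, ".json"))))
  write_voxels(tube, path)
  back <- read_voxels(path)
  expect_identical(back$grid, tube$grid)
  expect_equal(back$spacing, tube$spacing)
  expect_equal(back$origin, tube$origin)
})

test_that("OFF and PLY mesh files round-trip", {
  sph <- icosphere(1, radius = 2)
  off <- tempfile(fileext = ".off")
  on.exit(unlink(off))
  write_off(sph, off)
  back <- read_off(off)
  expect_equal(back$vertices, sph$vertices, tolerance = 1e-12)
  expect_identical(back$faces, sph$faces)

  ply <- tempfile(fileext = ".ply")
  on.exit(unlink(ply), add = TRUE)
  writeLines(c("ply", "format ascii 1.0",
               "element vertex 3",
               "property float x", "property float y", "property float z",
               "element face 1", "property list uchar int vertex_indices",
               "end_header",
               "0 0 0", "1 0 0", "0 1 0", "3 0 1 2"), ply)
  tri <- read_ply(ply)
  expect_identical(nrow(tri$vertices), 3L)
  expect_identical(tri$faces, matrix(c(1L, 2L, 3L), 1L))
})

test_that("PDB atom records gain van der Waals radii by element", {
  pdb_line <- function(serial, name, elem, x, y, z) {
    sprintf("ATOM  %5d %-4s ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, serial, x, y, z, elem)
  }
  path <- tempfile(fileext = ".pdb")
  on.exit(unlink(path))
  writeLines(c(pdb_line(1, "N", "N", 0, 0, 0),
               pdb_line(2, "CA", "C", 1.5, 0, 0),
               pdb_line(3, "O", "O", 3.0, 0, 0),
               "END"), path)
  at <- read_pdb_atoms(path)
  expect_identical(nrow(at), 3L)
  expect_equal(at$radius, c(1.55, 1.70, 1.52))
  expect_equal(at$x, c(0, 1.5, 3.0))
  vm <- voxelize_atoms(at, 24)
  expect_identical(n_components(vm), 1L)
  expect_gt(n_object_voxels(vm), 0L)
})
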