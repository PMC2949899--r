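#' Volumetric (voxel) model of a molecular shape
#'
#' A `voxel_model` is a uniform 3D lattice of binary occupancy: each lattice
#' point is either an object point (1, inside the shape) or a background point
#' (0, outside).  The lattice step (`spacing`) is isotropic and carries the
#' world length units; the world coordinate of lattice index `(i, j, k)`
#' (1-based) is `origin + (i - 1, j - 1, k - 1) * spacing`.  A non-empty model
#' never has object points on the outermost lattice layer, so every occupancy
#' test can inspect all 26 neighbours without bounds checks.
#'
#' @param grid 3D array of 0/1 occupancy values.
#' @param spacing positive lattice step in world units.
#' @param origin numeric length-3 world coordinate of lattice index (1,1,1).
#' @return An object of class `voxel_model` with fields `grid`, `dims`,
#'   `spacing`, `origin`.
#' @seealso [voxelize_mesh()], [voxelize_atoms()], [extract_boundary()]
#' @export
voxel_model <- function(grid, spacing, origin = c(0, 0, 0)) {
  if (!is.array(grid) || length(dim(grid)) != 3L) {
    stop("'grid' must be a 3D array", call. = FALSE)
  }
  storage.mode(grid) <- "integer"
  if (anyNA(grid) || !all(grid == 0L | grid == 1L)) {
    stop("every lattice value must be exactly 0 or 1", call. = FALSE)
  }
  if (!is.numeric(spacing) || length(spacing) != 1L || spacing <= 0) {
    stop("'spacing' must be a single positive number", call. = FALSE)
  }
  if (length(origin) != 3L || !is.numeric(origin)) {
    stop("'origin' must be a numeric vector of length 3", call. = FALSE)
  }
  d <- dim(grid)
  if (sum(grid) > 0L) {
    outer_occupied <-
      any(grid[c(1L, d[1L]), , ] == 1L) ||
      any(grid[, c(1L, d[2L]), ] == 1L) ||
      any(grid[, , c(1L, d[3L])] == 1L)
    if (outer_occupied) {
      stop("object points on the outermost lattice layer; pad the grid ",
           "so every voxel has 26 in-grid neighbours", call. = FALSE)
    }
  }
  structure(
    list(grid = grid, dims = d, spacing = as.numeric(spacing),
         origin = as.numeric(origin)),
    class = "voxel_model"
  )
}

#' @export
print.voxel_model <- function(x, ...) {
  cat("voxel_model: ", paste(x$dims, collapse = " x "),
      " lattice, spacing ", format(x$spacing, digits = 6),
      ", ", sum(x$grid), " object voxels\n", sep = "")
  invisible(x)
}

#' Number of object voxels in a model
#' @param model a [voxel_model()].
#' @return integer count of object points.
#' @export
n_object_voxels <- function(model) {
  stopifnot(inherits(model, "voxel_model"))
  sum(model$grid)
}

normalize_dims <- function(dims) {
  dims <- as.integer(dims)
  if (length(dims) == 1L) dims <- rep(dims, 3L)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 8L)) {
    stop("'dims' must be one or three integers >= 8", call. = FALSE)
  }
  dims
}

# Compact-fit contract shared by all rasterizers: isotropic spacing chosen so
# the longest bounding-box axis spans dims - 2 lattice planes, grid centred on
# the box, leaving a one-voxel background margin on every face.
compact_fit <- function(bbox_min, bbox_max, dims) {
  extent <- bbox_max - bbox_min
  if (any(extent < 0)) stop("degenerate bounding box", call. = FALSE)
  if (all(extent == 0)) stop("zero-volume input geometry", call. = FALSE)
  spacing <- max(extent / (dims - 2L))
  centre <- (bbox_min + bbox_max) / 2
  origin <- centre - (dims - 1L) / 2 * spacing
  list(spacing = spacing, origin = origin)
}

# World coordinates of all lattice points along each axis.
axis_coords <- function(dims, spacing, origin) {
  lapply(1:3, function(ax) origin[ax] + (seq_len(dims[ax]) - 1) * spacing)
}

#' Rasterize a union of spheres (atom list) onto a lattice
#'
#' A molecule given as atom centres and radii (for example van der Waals
#' spheres from a PDB file) is converted to a volumetric model: a lattice
#' point is an object point iff it lies inside at least one sphere.  The
#' sphere union is fitted compactly into the grid (isotropic spacing, centred,
#' one-voxel background margin).
#'
#' @param atoms data.frame or matrix with columns `x`, `y`, `z`, `radius`
#'   (world units).
#' @param dims lattice size: one or three integers, each >= 8 (default 64).
#' @param spacing,origin optionally force the lattice geometry instead of
#'   compact fitting (both must be given together); object points falling
#'   outside the grid raise an error.
#' @return A [voxel_model()].
#' @export
voxelize_atoms <- function(atoms, dims = 64L, spacing = NULL, origin = NULL) {
  atoms <- as.data.frame(atoms)
  needed <- c("x", "y", "z", "radius")
  if (!all(needed %in% names(atoms))) {
    stop("'atoms' needs columns x, y, z, radius", call. = FALSE)
  }
  if (nrow(atoms) < 1L) stop("empty atom list", call. = FALSE)
  if (any(atoms$radius <= 0)) stop("all radii must be > 0", call. = FALSE)
  dims <- normalize_dims(dims)
  ctr <- as.matrix(atoms[, c("x", "y", "z")])
  r <- atoms$radius
  if (is.null(spacing)) {
    fit <- compact_fit(apply(ctr - r, 2, min), apply(ctr + r, 2, max), dims)
    spacing <- fit$spacing
    origin <- fit$origin
  }
  ax <- axis_coords(dims, spacing, origin)
  grid <- array(0L, dims)
  for (a in seq_len(nrow(atoms))) {
    # restrict the distance test to the sphere's bounding sub-box
    rng <- lapply(1:3, function(k) {
      which(ax[[k]] >= ctr[a, k] - r[a] & ax[[k]] <= ctr[a, k] + r[a])
    })
    if (any(lengths(rng) == 0L)) next
    dx2 <- (ax[[1]][rng[[1]]] - ctr[a, 1])^2
    dy2 <- (ax[[2]][rng[[2]]] - ctr[a, 2])^2
    dz2 <- (ax[[3]][rng[[3]]] - ctr[a, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    sub <- grid[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
    sub[d2 <= r[a]^2] <- 1L
    grid[rng[[1]], rng[[2]], rng[[3]]] <- sub
  }
  if (sum(grid) == 0L) stop("rasterization produced an empty model", call. = FALSE)
  voxel_model(grid, spacing, origin)
}

# The 26-neighbourhood offsets (excluding the null offset).
neighbour_offsets_26 <- function() {
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  off[rowSums(abs(off)) > 0L, , drop = FALSE]
}

#' Boundary point set of a volumetric model
#'
#' An object point lies on the boundary surface if at least one of its 26
#' lattice neighbours is a background point.  Points are returned in
#' deterministic lexicographic index order (first axis fastest).
#'
#' @param model a non-empty [voxel_model()].
#' @return An object of class `boundary_points`: `indices` (n x 3 integer
#'   lattice indices, 1-based), `points` (n x 3 world coordinates), plus the
#'   model's `dims`, `spacing`, `origin`.
#' @export
extract_boundary <- function(model) {
  stopifnot(inherits(model, "voxel_model"))
  g <- model$grid
  if (sum(g) == 0L) stop("empty model has no boundary", call. = FALSE)
  d <- model$dims
  has_bg <- array(FALSE, d)
  offs <- neighbour_offsets_26()
  for (o in seq_len(nrow(offs))) {
    off <- offs[o, ]
    # neighbour occupancy with zero fill (outside the grid = background);
    # the padding invariant means the fill is never consulted for object points
    shifted <- array(0L, d)
    src <- lapply(1:3, function(ax) {
      i <- seq_len(d[ax]) + off[ax]
      i[i >= 1L & i <= d[ax]]
    })
    dst <- lapply(1:3, function(ax) {
      i <- seq_len(d[ax])
      i[i + off[ax] >= 1L & i + off[ax] <= d[ax]]
    })
    shifted[dst[[1]], dst[[2]], dst[[3]]] <-
      g[src[[1]], src[[2]], src[[3]], drop = FALSE]
    has_bg <- has_bg | (shifted == 0L)
  }
  sel <- g == 1L & has_bg
  idx <- which(sel, arr.ind = TRUE)
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  pts <- sweep((idx - 1) * model$spacing, 2, model$origin, "+")
  structure(
    list(indices = idx, points = pts, dims = d,
         spacing = model$spacing, origin = model$origin),
    class = "boundary_points"
  )
}

#' @export
print.boundary_points <- function(x, ...) {
  cat("boundary_points: ", nrow(x$indices), " surface voxels\n", sep = "")
  invisible(x)
}

#' Rotate a voxel model by multiples of 90 degrees about a lattice axis
#'
#' Voxel-exact rotation of the occupancy grid about its centre; used to probe
#' descriptor invariance.  The world origin is kept, i.e. the rotation is a
#' relabelling of the lattice.
#'
#' @param model a [voxel_model()] with a cubic grid.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param times number of quarter turns (integer, may be negative).
#' @return The rotated [voxel_model()].
#' @export
rotate_model_90 <- function(model, axis = c("z", "x", "y"), times = 1L) {
  stopifnot(inherits(model, "voxel_model"))
  axis <- match.arg(axis)
  d <- model$dims
  if (length(unique(d)) != 1L) {
    stop("90-degree rotation requires a cubic grid", call. = FALSE)
  }
  g <- model$grid
  times <- ((as.integer(times) %% 4L) + 4L) %% 4L
  quarter <- function(g, axis) {
    switch(axis,
      # (i,j,k) -> (j, n-i+1, k)
      z = aperm(g, c(2L, 1L, 3L))[, rev(seq_len(dim(g)[1L])), , drop = FALSE],
      # (i,j,k) -> (i, k, n-j+1)
      x = aperm(g, c(1L, 3L, 2L))[, , rev(seq_len(dim(g)[2L])), drop = FALSE],
      # (i,j,k) -> (n-k+1, j, i)
      y = aperm(g, c(3L, 2L, 1L))[rev(seq_len(dim(g)[3L])), , , drop = FALSE]
    )
  }
  for (t in seq_len(times)) g <- quarter(g, axis)
  voxel_model(g, model$spacing, model$origin)
}

#' Number of 26-connected components among object voxels
#'
#' @param model a [voxel_model()].
#' @return Integer component count (0 for an empty model).
#' @export
n_components <- function(model) {
  stopifnot(inherits(model, "voxel_model"))
  if (sum(model$grid) == 0L) return(0L)
  vg <- build_voxel_graph(model)
  as.integer(igraph::count_components(vg$graph))
}

#' Write / read a voxel model as portable text
#'
#' The raster file holds one text line per lattice row: for slice `k` (slowest
#' index) and column `j`, line `(k - 1) * dims[2] + j` is a string of
#' `dims[1]` characters, each `0` or `1`, giving occupancy for `i = 1..dims[1]`.
#' A JSON sidecar at `<path>.json` records `dims`, `spacing` and `origin`, so
#' other tools can reconstruct the lattice geometry.
#'
#' @param model a [voxel_model()].
#' @param path raster file path; the sidecar is written next to it.
#' @return `write_voxels` returns `path` invisibly; `read_voxels` returns the
#'   [voxel_model()].
#' @export
write_voxels <- function(model, path) {
  stopifnot(inherits(model, "voxel_model"))
  d <- model$dims
  m <- matrix(as.character(model$grid), nrow = d[1L])  # columns = (j,k) pairs
  lines <- apply(m, 2L, paste0, collapse = "")
  writeLines(lines, path)
  jsonlite::write_json(
    list(dims = d, spacing = model$spacing, origin = model$origin),
    paste0(path, ".json"),
    auto_unbox = FALSE, digits = NA
  )
  invisible(path)
}

#' @rdname write_voxels
#' @export
read_voxels <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  d <- as.integer(side$dims)
  lines <- readLines(path)
  if (length(lines) != d[2L] * d[3L]) {
    stop("raster file does not match sidecar dims", call. = FALSE)
  }
  digits <- as.integer(unlist(strsplit(lines, "", fixed = TRUE), use.names = FALSE))
  voxel_model(array(digits, d), side$spacing, side$origin)
}
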