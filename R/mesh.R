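#' Triangle surface meshes
#'
#' Minimal closed-triangle-mesh container used as rasterization input.
#'
#' @param vertices numeric V x 3 matrix of vertex coordinates.
#' @param faces integer F x 3 matrix of 1-based vertex indices.
#' @return An object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L || nrow(vertices) < 3L) {
    stop("'vertices' must be a V x 3 matrix with V >= 3", call. = FALSE)
  }
  if (ncol(faces) != 3L || nrow(faces) < 1L) {
    stop("'faces' must be an F x 3 matrix with F >= 1", call. = FALSE)
  }
  if (anyNA(faces) || any(faces < 1L) || any(faces > nrow(vertices))) {
    stop("face indices out of range", call. = FALSE)
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat("triangle_mesh: ", nrow(x$vertices), " vertices, ",
      nrow(x$faces), " faces\n", sep = "")
  invisible(x)
}

#' Check that a triangle mesh is watertight (closed and orientable)
#'
#' Every undirected edge must be shared by exactly two faces, and the two
#' incident faces must traverse it in opposite directions.
#'
#' @param mesh a [triangle_mesh()].
#' @return `TRUE` or `FALSE`; the failure reason is in attribute `"reason"`.
#' @export
mesh_is_watertight <- function(mesh) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  f <- mesh$faces
  he <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])  # directed half-edges
  if (any(he[, 1] == he[, 2])) {
    return(structure(FALSE, reason = "degenerate face (repeated vertex)"))
  }
  und <- paste(pmin(he[, 1], he[, 2]), pmax(he[, 1], he[, 2]))
  cnt <- table(und)
  if (any(cnt != 2L)) {
    return(structure(FALSE, reason = sprintf(
      "%d edge(s) not shared by exactly two faces", sum(cnt != 2L))))
  }
  dir_keys <- paste(he[, 1], he[, 2])
  if (anyDuplicated(dir_keys)) {
    return(structure(FALSE, reason = "inconsistent face orientation"))
  }
  TRUE
}

#' Read and write triangle meshes in OFF and ASCII PLY formats
#'
#' @param path file path.
#' @return A [triangle_mesh()] (readers) or `path` invisibly (writer).
#' @export
read_off <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (toupper(toks[1L]) != "OFF") stop("not an OFF file", call. = FALSE)
  nv <- as.integer(toks[2L]); nf <- as.integer(toks[3L])
  pos <- 5L  # after OFF nv nf ne
  v <- matrix(as.numeric(toks[pos:(pos + 3L * nv - 1L)]), ncol = 3L, byrow = TRUE)
  pos <- pos + 3L * nv
  f <- matrix(NA_integer_, nf, 3L)
  for (i in seq_len(nf)) {
    k <- as.integer(toks[pos])
    if (k != 3L) stop("only triangle faces are supported", call. = FALSE)
    f[i, ] <- as.integer(toks[(pos + 1L):(pos + 3L)]) + 1L
    pos <- pos + 1L + k
  }
  triangle_mesh(v, f)
}

#' @rdname read_off
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1L, function(r)
    paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1L, function(r)
    paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

#' @rdname read_off
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (trimws(lines[1L]) != "ply") stop("not a PLY file", call. = FALSE)
  fmt <- grep("^format", lines, value = TRUE)
  if (!grepl("ascii", fmt[1L])) {
    stop("only ASCII PLY is supported", call. = FALSE)
  }
  end <- grep("^end_header", lines)[1L]
  nv <- as.integer(sub(".*vertex\\s+", "", grep("^element vertex", lines, value = TRUE)[1L]))
  nf <- as.integer(sub(".*face\\s+", "", grep("^element face", lines, value = TRUE)[1L]))
  body <- lines[(end + 1L):length(lines)]
  vtoks <- strsplit(trimws(body[seq_len(nv)]), "\\s+")
  v <- t(vapply(vtoks, function(t) as.numeric(t[1:3]), numeric(3L)))
  ftoks <- strsplit(trimws(body[nv + seq_len(nf)]), "\\s+")
  f <- t(vapply(ftoks, function(t) {
    if (as.integer(t[1L]) != 3L) stop("only triangle faces are supported", call. = FALSE)
    as.integer(t[2:4]) + 1L
  }, integer(3L)))
  triangle_mesh(v, f)
}

#' Icosphere mesh (subdivided icosahedron)
#'
#' Watertight triangulated sphere used as a mesh-pipeline fixture.
#'
#' @param subdivisions number of 4-to-1 triangle subdivisions (0-4).
#' @param radius sphere radius in world units.
#' @return A [triangle_mesh()] whose vertices lie on the sphere.
#' @export
icosphere <- function(subdivisions = 2L, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE)
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- mid_cache[[key]]
      if (!is.null(id)) return(id)
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      id <- nrow(v)
      mid_cache[[key]] <- id
      id
    }
    nf <- matrix(NA_integer_, 0L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; c3 <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, c3); ca <- midpoint(c3, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c3, ca, bc), c(ab, bc, ca))
    }
    f <- nf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  triangle_mesh(v, f)
}

#' Rasterize a closed triangle mesh onto a lattice
#'
#' The mesh bounding box is fitted compactly into the grid (isotropic spacing,
#' centred, one-voxel background margin); a lattice point is an object point
#' iff its centre lies inside the surface, decided by ray-casting parity along
#' the +x direction.  Ray origins are offset by a tiny fraction of the spacing
#' to avoid grazing triangle edges of axis-aligned geometry.
#'
#' @param mesh a watertight [triangle_mesh()].
#' @param dims lattice size: one or three integers, each >= 8 (default 64).
#' @param spacing,origin optionally force the lattice geometry (see
#'   [voxelize_atoms()]).
#' @return A [voxel_model()].
#' @export
voxelize_mesh <- function(mesh, dims = 64L, spacing = NULL, origin = NULL) {
  stopifnot(inherits(mesh, "triangle_mesh"))
  wt <- mesh_is_watertight(mesh)
  if (!isTRUE(wt)) {
    stop("mesh is not watertight: ", attr(wt, "reason"), call. = FALSE)
  }
  dims <- normalize_dims(dims)
  v <- mesh$vertices
  if (is.null(spacing)) {
    fit <- compact_fit(apply(v, 2, min), apply(v, 2, max), dims)
    spacing <- fit$spacing
    origin <- fit$origin
  }
  ax <- axis_coords(dims, spacing, origin)
  eps <- spacing * 2.3283064365386963e-08  # keep rays off lattice-aligned edges
  ys <- ax[[2]] + eps
  zs <- ax[[3]] + sqrt(2) * eps
  f <- mesh$faces
  # crossing x-coordinates per (j, k) ray column
  cross_col <- vector("list", dims[2L] * dims[3L])
  for (t in seq_len(nrow(f))) {
    p1 <- v[f[t, 1L], ]; p2 <- v[f[t, 2L], ]; p3 <- v[f[t, 3L], ]
    e1 <- p2 - p1; e2 <- p3 - p1
    det <- e1[2L] * e2[3L] - e1[3L] * e2[2L]
    if (abs(det) < .Machine$double.eps * 64) next  # edge-on in yz projection
    jr <- which(ys >= min(p1[2L], p2[2L], p3[2L]) & ys <= max(p1[2L], p2[2L], p3[2L]))
    kr <- which(zs >= min(p1[3L], p2[3L], p3[3L]) & zs <= max(p1[3L], p2[3L], p3[3L]))
    if (!length(jr) || !length(kr)) next
    qy <- rep(ys[jr], times = length(kr)) - p1[2L]
    qz <- rep(zs[kr], each = length(jr)) - p1[3L]
    u <- (qy * e2[3L] - qz * e2[2L]) / det
    w <- (e1[2L] * qz - e1[3L] * qy) / det
    hit <- u >= 0 & w >= 0 & (u + w) <= 1
    if (!any(hit)) next
    xh <- p1[1L] + u[hit] * e1[1L] + w[hit] * e2[1L]
    cols <- (rep(kr, each = length(jr)) - 1L) * dims[2L] + rep(jr, times = length(kr))
    cols <- cols[hit]
    for (ii in seq_along(cols)) {
      cross_col[[cols[ii]]] <- c(cross_col[[cols[ii]]], xh[ii])
    }
  }
  grid <- array(0L, dims)
  xs <- ax[[1]]
  for (col in which(lengths(cross_col) > 0L)) {
    k <- (col - 1L) %/% dims[2L] + 1L
    j <- col - (k - 1L) * dims[2L]
    xc <- cross_col[[col]]
    inside <- (vapply(xs, function(x) sum(xc > x), integer(1L)) %% 2L) == 1L
    grid[inside, j, k] <- 1L
  }
  if (sum(grid) == 0L) {
    stop("rasterization produced an empty model (mesh thinner than one voxel?)",
         call. = FALSE)
  }
  voxel_model(grid, spacing, origin)
}
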