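#' Weighted 26-connectivity graph over object voxels
#'
#' Nodes are all object voxels (interior and boundary), so shortest paths may
#' pass through the interior of the shape: this is what makes the resulting
#' metric an inner distance rather than a surface geodesic.  Edges connect
#' 26-adjacent object voxels and are weighted by the Euclidean step length in
#' world units (`spacing`, `spacing * sqrt(2)` or `spacing * sqrt(3)`).
#'
#' @param model a non-empty [voxel_model()].
#' @param boundary_only restrict nodes to boundary voxels; paths are then
#'   confined to the voxelized surface shell, giving the geodesic-distance
#'   baseline rather than the inner distance.
#' @return An object of class `voxel_graph`: an igraph `graph` with edge
#'   weights, `indices` (node lattice indices in node order), `node_of` (array
#'   mapping lattice linear index to node id), plus lattice geometry fields.
#' @export
build_voxel_graph <- function(model, boundary_only = FALSE) {
  stopifnot(inherits(model, "voxel_model"))
  d <- model$dims
  occ <- model$grid
  if (boundary_only) {
    b <- extract_boundary(model)
    occ <- array(0L, d)
    occ[b$indices] <- 1L
  }
  if (sum(occ) == 0L) stop("empty model", call. = FALSE)
  idx <- which(occ == 1L, arr.ind = TRUE)
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  nv <- nrow(idx)
  node_of <- array(0L, d)
  node_of[occ == 1L] <- seq_len(nv)

  offs <- neighbour_offsets_26()
  offs <- offs[offs[, 1L] > 0L |
               (offs[, 1L] == 0L & offs[, 2L] > 0L) |
               (offs[, 1L] == 0L & offs[, 2L] == 0L & offs[, 3L] > 0L), ,
               drop = FALSE]  # one direction per unordered pair
  from <- integer(0)
  to <- integer(0)
  wts <- numeric(0)
  for (o in seq_len(nrow(offs))) {
    off <- offs[o, ]
    nb <- idx + rep(off, each = nv)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
          nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
          nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    if (!any(ok)) next
    nb_lin <- nb[ok, 1L] + (nb[ok, 2L] - 1L) * d[1L] +
      (nb[ok, 3L] - 1L) * d[1L] * d[2L]
    tgt <- node_of[nb_lin]
    keep <- tgt > 0L
    if (!any(keep)) next
    from <- c(from, which(ok)[keep])
    to <- c(to, tgt[keep])
    wts <- c(wts, rep(model$spacing * sqrt(sum(off^2)), sum(keep)))
  }
  g <- igraph::make_graph(rbind(from, to), n = nv, directed = FALSE)
  igraph::E(g)$weight <- wts
  structure(
    list(graph = g, indices = idx, node_of = node_of, dims = d,
         spacing = model$spacing, origin = model$origin,
         boundary_only = isTRUE(boundary_only)),
    class = "voxel_graph"
  )
}

#' @export
print.voxel_graph <- function(x, ...) {
  cat("voxel_graph: ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges",
      if (x$boundary_only) " (boundary shell only)", "\n", sep = "")
  invisible(x)
}

node_ids_of_samples <- function(graph, samples) {
  lin <- samples$lattice[, 1L] +
    (samples$lattice[, 2L] - 1L) * graph$dims[1L] +
    (samples$lattice[, 3L] - 1L) * graph$dims[1L] * graph$dims[2L]
  ids <- graph$node_of[lin]
  if (any(ids == 0L)) {
    stop("some sample points are not nodes of the voxel graph", call. = FALSE)
  }
  ids
}

#' Inner-distance matrix between landmark points
#'
#' Exact shortest-path lengths (Dijkstra, one single-source run per landmark)
#' through the object-voxel graph, in world units.  The inner distance between
#' two boundary points is the length of the shortest path connecting them
#' within the shape volume.
#'
#' @param graph a [build_voxel_graph()] result.
#' @param samples a [sample_uniform()] / [sample_random()] result on the same
#'   model.
#' @param on_disconnected what to do when samples fall into different
#'   connected components: `"error"` (default) aborts and reports the
#'   partition; `"largest"` keeps only the samples in the largest component
#'   (with a warning) and returns the reduced matrix plus attribute
#'   `"kept"` giving the retained sample positions.
#' @return Symmetric n x n matrix with zero diagonal and attribute
#'   `kind = "inner"` (or `"geodesic"` for a boundary-only graph).
#' @export
inner_distance_matrix <- function(graph, samples,
                                  on_disconnected = c("error", "largest")) {
  stopifnot(inherits(graph, "voxel_graph"), inherits(samples, "sample_points"))
  on_disconnected <- match.arg(on_disconnected)
  ids <- node_ids_of_samples(graph, samples)
  comp <- igraph::components(graph$graph)
  mem <- comp$membership[ids]
  kept <- seq_along(ids)
  if (length(unique(mem)) > 1L) {
    sizes <- table(mem)
    msg <- paste0("samples span ", length(sizes), " connected components (",
                  paste(sprintf("component %s: %d samples", names(sizes), sizes),
                        collapse = "; "), ")")
    if (on_disconnected == "error") stop(msg, call. = FALSE)
    big <- names(sizes)[which.max(sizes)]
    warning(msg, "; keeping the largest", call. = FALSE)
    kept <- which(mem == as.integer(big))
    ids <- ids[kept]
  }
  D <- igraph::distances(graph$graph, v = ids, to = ids, mode = "out",
                         algorithm = "dijkstra")
  dimnames(D) <- NULL
  # Dijkstra accumulates path sums in traversal order; enforce exact symmetry
  # by taking the per-pair minimum (both entries are the same graph metric).
  D <- pmin(D, t(D))
  if (any(!is.finite(D))) stop("non-finite inner distances", call. = FALSE)
  attr(D, "kind") <- if (graph$boundary_only) "geodesic" else "inner"
  if (length(kept) < samples$n) attr(D, "kept") <- kept
  D
}

#' Euclidean distance matrix between landmark points
#'
#' Straight-line world distances; the baseline "D2" descriptor input and the
#' lower bound of the inner distance.
#'
#' @param samples a `sample_points` object.
#' @return Symmetric n x n matrix, zero diagonal, attribute `kind = "euclidean"`.
#' @export
euclidean_distance_matrix <- function(samples) {
  stopifnot(inherits(samples, "sample_points"))
  L <- samples$lattice
  storage.mode(L) <- "double"
  n <- nrow(L)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    D[, i] <- samples$spacing *
      sqrt(sum3_sorted((L[, 1L] - L[i, 1L])^2,
                       (L[, 2L] - L[i, 2L])^2,
                       (L[, 3L] - L[i, 3L])^2))
  }
  D <- pmin(D, t(D))
  attr(D, "kind") <- "euclidean"
  D
}

#' @rdname inner_distance_matrix
#' @export
dist_kind <- function(D) attr(D, "kind") %||% "unknown"
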