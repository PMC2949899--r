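#' Landmark sampling on the boundary surface
#'
#' `sample_uniform()` picks `n` uniformly spread landmark points on a boundary
#' point set with Lloyd's algorithm (k-means, k = n) on the lattice
#' coordinates, then snaps each cluster centroid to its nearest member
#' boundary point so every landmark lies on the surface.  `sample_random()`
#' draws `n` boundary points uniformly without replacement and exists for
#' comparison with uniform sampling.
#'
#' All cluster arithmetic is carried out on integer lattice coordinates with
#' permutation-invariant summation, and candidate points are processed in a
#' rotation-invariant canonical order.  Given the same seed, the selected
#' landmark set is therefore exactly equivariant under voxel-exact 90-degree
#' rotations of the model (up to genuinely symmetric tie orbits), which is
#' what makes full-pipeline descriptors bit-reproducible under such rotations.
#'
#' @param boundary a `boundary_points` object from [extract_boundary()].
#' @param n number of landmarks (2 <= n <= number of boundary points).
#' @param seed integer RNG seed; the sampler restores the caller's RNG state.
#' @param iter_max maximum Lloyd iterations (default 300); iteration stops as
#'   soon as cluster assignments are stable.
#' @return An object of class `sample_points`: `points` (n x 3 world
#'   coordinates), `lattice` (n x 3 integer lattice indices), `source_indices`
#'   (rows into `boundary$points`), `n`, `seed`, `method`, `spacing`.
#' @export
sample_uniform <- function(boundary, n, seed, iter_max = 300L) {
  check_sampling_args(boundary, n)
  N <- nrow(boundary$indices)
  ord <- boundary_canonical_order(boundary$indices)
  P <- boundary$indices[ord, , drop = FALSE]
  storage.mode(P) <- "double"

  if (n == N) {
    return(new_sample_points(boundary, ord, n, seed, "lloyd"))
  }

  centers_idx <- with_seed(seed, kmeanspp_init(P, n))
  assign_vec <- rep(NA_integer_, N)
  # initial centers are single points
  Sj <- P[centers_idx, , drop = FALSE]
  cj <- rep(1, n)
  best_d <- NULL
  for (it in seq_len(iter_max)) {
    res <- assign_points(P, Sj, cj)
    new_assign <- res$assign
    best_d <- res$dist
    # re-seed any emptied cluster at the worst-served point
    repeat {
      counts <- tabulate(new_assign, nbins = n)
      empty <- which(counts == 0L)
      if (!length(empty)) break
      worst <- which.max(best_d)
      new_assign[worst] <- empty[1L]
      best_d[worst] <- 0
    }
    if (identical(new_assign, assign_vec)) break
    assign_vec <- new_assign
    Sj <- rowsum(P, assign_vec, reorder = TRUE)
    cj <- as.numeric(tabulate(assign_vec, nbins = n))
  }
  picked <- snap_to_members(P, assign_vec, Sj, cj, n)
  new_sample_points(boundary, ord[picked], n, seed, "lloyd")
}

#' @rdname sample_uniform
#' @export
sample_random <- function(boundary, n, seed) {
  check_sampling_args(boundary, n)
  N <- nrow(boundary$indices)
  ord <- boundary_canonical_order(boundary$indices)
  picked <- with_seed(seed, sample.int(N, n))
  new_sample_points(boundary, ord[picked], n, seed, "random")
}

#' @export
print.sample_points <- function(x, ...) {
  cat("sample_points: n = ", x$n, " (", x$method, " sampling, seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

check_sampling_args <- function(boundary, n) {
  if (!inherits(boundary, "boundary_points")) {
    stop("'boundary' must come from extract_boundary()", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 2L) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  if (n > nrow(boundary$indices)) {
    stop("n = ", n, " exceeds the number of boundary points (",
         nrow(boundary$indices), ")", call. = FALSE)
  }
}

new_sample_points <- function(boundary, rows, n, seed, method) {
  structure(
    list(points = boundary$points[rows, , drop = FALSE],
         lattice = boundary$indices[rows, , drop = FALSE],
         source_indices = as.integer(rows),
         n = as.integer(n), seed = as.integer(seed), method = method,
         spacing = boundary$spacing),
    class = "sample_points"
  )
}

# Rotation-invariant canonical ordering of lattice points.  Coordinates are
# centred on the exact (N-scaled, hence integer) centroid; among the 48
# signed axis permutations, the frame whose lexicographically sorted
# coordinate list is minimal is the canonical frame, and points are returned
# in its sort order.  Two models related by any voxel-exact rotation or
# reflection then enumerate corresponding points in corresponding order, so
# seeded sampling on integer coordinates is exactly equivariant.
boundary_canonical_order <- function(idx) {
  N <- nrow(idx)
  I <- matrix(as.numeric(idx), ncol = 3L)
  S <- colSums(I)
  C <- sweep(N * I, 2L, S, "-")  # exact integers
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  signs <- as.matrix(expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1)))
  best_flat <- NULL
  best_ord <- NULL
  for (p in perms) {
    for (si in seq_len(nrow(signs))) {
      V <- C[, p, drop = FALSE]
      V[, 1L] <- signs[si, 1L] * V[, 1L]
      V[, 2L] <- signs[si, 2L] * V[, 2L]
      V[, 3L] <- signs[si, 3L] * V[, 3L]
      o <- order(V[, 1L], V[, 2L], V[, 3L], method = "radix")
      flat <- as.vector(t(V[o, , drop = FALSE]))
      if (is.null(best_flat)) {
        best_flat <- flat
        best_ord <- o
      } else {
        k <- which(flat != best_flat)[1L]
        if (!is.na(k) && flat[k] < best_flat[k]) {
          best_flat <- flat
          best_ord <- o
        }
      }
    }
  }
  best_ord
}

# kmeans++-style seeded initialisation on integer lattice coordinates;
# squared distances are exact integers, so selection probabilities are
# identical across rotated frames.
kmeanspp_init <- function(P, k) {
  N <- nrow(P)
  centers <- integer(k)
  centers[1L] <- sample.int(N, 1L)
  d2 <- sqdist_to_point(P, P[centers[1L], ])
  for (j in seq_len(k - 1L) + 1L) {
    tot <- sum(d2)
    centers[j] <- if (tot > 0) {
      sample.int(N, 1L, prob = d2)
    } else {
      setdiff(seq_len(N), centers[seq_len(j - 1L)])[1L]
    }
    d2 <- pmin(d2, sqdist_to_point(P, P[centers[j], ]))
  }
  centers
}

# Nearest-centre assignment with exact integer arithmetic: the squared
# distance of point p to centroid S_j / c_j is computed as
# sum_axis (c_j p - S_j)^2 / c_j^2, every term an exactly representable
# integer before the final division.  Ties keep the lower cluster index.
assign_points <- function(P, Sj, cj) {
  N <- nrow(P)
  best_d <- rep(Inf, N)
  best_j <- rep(1L, N)
  for (j in seq_len(nrow(Sj))) {
    t1 <- cj[j] * P[, 1L] - Sj[j, 1L]
    t2 <- cj[j] * P[, 2L] - Sj[j, 2L]
    t3 <- cj[j] * P[, 3L] - Sj[j, 3L]
    d <- sum3_sorted(t1 * t1, t2 * t2, t3 * t3) / (cj[j] * cj[j])
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_j[upd] <- j
  }
  list(assign = best_j, dist = best_d)
}

# Snap each centroid to its nearest member point (ties: first member in
# canonical order).  Members partition the point set, so picks are distinct.
snap_to_members <- function(P, assign_vec, Sj, cj, k) {
  picked <- integer(k)
  members <- split(seq_len(nrow(P)), assign_vec)
  for (j in seq_len(k)) {
    mem <- members[[as.character(j)]]
    t1 <- cj[j] * P[mem, 1L] - Sj[j, 1L]
    t2 <- cj[j] * P[mem, 2L] - Sj[j, 2L]
    t3 <- cj[j] * P[mem, 3L] - Sj[j, 3L]
    d <- sum3_sorted(t1 * t1, t2 * t2, t3 * t3)
    picked[j] <- mem[which.min(d)]
  }
  picked
}
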