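# Fixture builders and independent oracles used across the test files.
# Everything is generated in code at test time; no stored data.

# Random 26-connected voxel solid grown by seeded accretion: each new voxel
# is a 26-neighbour of an existing one, so connectivity holds by construction.
rand_solid <- function(n_voxels, seed, dims = 16L, spacing = 1) {
  set.seed(seed)
  dims <- rep(dims, length.out = 3L)
  occ <- array(0L, dims)
  centre <- floor(dims / 2) + 1L
  cells <- matrix(centre, nrow = 1L)
  occ[matrix(centre, 1L)] <- 1L
  while (nrow(cells) < n_voxels) {
    base <- cells[sample.int(nrow(cells), 1L), ]
    cand <- base + sample(c(-1L, 0L, 1L), 3L, replace = TRUE)
    if (any(cand < 2L) || any(cand > dims - 1L)) next
    if (occ[matrix(cand, 1L)] == 1L) next
    occ[matrix(cand, 1L)] <- 1L
    cells <- rbind(cells, cand)
  }
  voxel_model(occ, spacing)
}

# All-pairs shortest paths over object voxels by Floyd-Warshall on the
# brute-force 26-adjacency matrix; the independent oracle for Dijkstra.
fw_distances <- function(model) {
  idx <- which(model$grid == 1L, arr.ind = TRUE)
  storage.mode(idx) <- "double"
  step <- as.matrix(stats::dist(idx))
  adj <- step > 0 & step <= sqrt(3) + 1e-9
  D <- matrix(Inf, nrow(idx), nrow(idx))
  D[adj] <- model$spacing * step[adj]
  diag(D) <- 0
  for (k in seq_len(nrow(idx))) {
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  }
  list(D = D, indices = idx)
}

# Rows of the oracle matrix corresponding to a sample set.
fw_rows_of_samples <- function(fw, samples) {
  key <- function(m) paste(m[, 1L], m[, 2L], m[, 3L])
  match(key(samples$lattice), key(fw$indices))
}

# Random Gaussian kernel from jittered 3D point clouds.
rand_kernel <- function(n, seed, sigma = "auto") {
  set.seed(seed)
  D <- as.matrix(stats::dist(matrix(stats::rnorm(3L * n), ncol = 3L)))
  attr(D, "kind") <- "euclidean"
  gaussian_kernel(D, sigma = sigma)
}

# Literal m-step evaluation of the random-walk diffusion distance:
# d_m(x, y)^2 = sum_z (P_sym^m[x, z] - P_sym^m[y, z])^2, with the matrix
# power computed by repeated multiplication.  Independent of the spectral
# implementation it checks.
direct_diffusion_distances <- function(P_sym, m) {
  Pm <- diag(nrow(P_sym))
  for (i in seq_len(m)) Pm <- Pm %*% P_sym
  n <- nrow(Pm)
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      D[i, j] <- D[j, i] <- sqrt(sum((Pm[i, ] - Pm[j, ])^2))
    }
  }
  D
}

# Hand construction of a descriptor object for metric arithmetic tests.
manual_descriptor <- function(bins) {
  structure(
    list(bins = bins / sum(bins), n_bin = length(bins), range = c(0, 1),
         n_values = sum(bins), meta = list()),
    class = "shape_descriptor"
  )
}

# Hand construction of a retrieval run (ids ranked by given order).
manual_run <- function(query_id, ranked_ids, scores = seq_along(ranked_ids)) {
  structure(
    list(query_id = query_id, ranked_ids = ranked_ids, scores = scores,
         metric = "L1"),
    class = "retrieval_run"
  )
}

# Largest pairwise L1 distance within a list of descriptors.
max_pairwise_l1 <- function(descs) {
  k <- length(descs)
  worst <- 0
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      worst <- max(worst, compare_descriptors(descs[[i]], descs[[j]], "L1"))
    }
  }
  worst
}

# Shared desk-scale benchmark, built once per test session (used by the
# topology-robustness and toy-retrieval acceptance tests).
.bench_cache <- new.env(parent = emptyenv())
acceptance_benchmark <- function() {
  if (is.null(.bench_cache$bench)) {
    .bench_cache$bench <- synthetic_benchmark(dims = 48L, n = 250L, m = 50L,
                                              n_bin = 128L, seed = 1L)
  }
  .bench_cache$bench
}
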