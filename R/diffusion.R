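#' Gaussian kernel on a pairwise distance matrix
#'
#' Builds the diffusion kernel `K(i, j) = exp(-D(i, j)^2 / sigma^2)`.  With
#' `sigma = "auto"` the width is set to the mean of the distances over all
#' unordered off-diagonal pairs, the method's standard calibration for inner
#' distances.  The kernel depends on distances only through `D / sigma`, so
#' jointly rescaling `D` and `sigma` leaves it unchanged.
#'
#' @param D symmetric nonnegative distance matrix with zero diagonal
#'   (typically from [inner_distance_matrix()]).
#' @param sigma positive bandwidth in the units of `D`, or `"auto"`.
#' @return Object of class `kernel_matrix`: `K` (values in (0, 1], unit
#'   diagonal), `sigma`, `base_metric`.
#' @export
gaussian_kernel <- function(D, sigma = "auto") {
  if (!is.matrix(D) || nrow(D) != ncol(D)) {
    stop("'D' must be a square matrix", call. = FALSE)
  }
  if (max(abs(D - t(D))) > 1e-8 * max(1, max(abs(D)))) {
    stop("'D' must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(D)) > 0)) stop("'D' must have a zero diagonal", call. = FALSE)
  if (identical(sigma, "auto")) {
    sigma <- mean(D[upper.tri(D)])
    if (!is.finite(sigma) || sigma <= 0) {
      stop("'auto' bandwidth failed: mean off-diagonal distance is not positive",
           call. = FALSE)
    }
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0) {
    stop("'sigma' must be a single positive number or \"auto\"", call. = FALSE)
  }
  K <- exp(-(D / sigma)^2)
  structure(
    list(K = K, sigma = as.numeric(sigma), base_metric = dist_kind(D)),
    class = "kernel_matrix"
  )
}

#' Markov transition matrices of the kernel random walk
#'
#' Row-normalizes the kernel into the single-step transition matrix
#' `P(i, j) = K(i, j) / v(i)` with `v(i)` the i-th row sum, and forms the
#' symmetric conjugate `P_sym(i, j) = K(i, j) / sqrt(v(i) v(j))`, which shares
#' the eigenvalues of `P` and satisfies
#' `P_sym = D^{1/2} P D^{-1/2}` with `D = diag(v)`.
#'
#' @param K a [gaussian_kernel()] result (or bare symmetric positive matrix).
#' @return Object of class `transition_matrices`: `P` (row-stochastic),
#'   `P_sym` (symmetric), `v` (row sums), `sigma`, `base_metric`.
#' @export
transition_matrices <- function(K) {
  sigma <- NA_real_
  base <- "unknown"
  if (inherits(K, "kernel_matrix")) {
    sigma <- K$sigma
    base <- K$base_metric
    K <- K$K
  }
  if (!is.matrix(K) || nrow(K) != ncol(K)) {
    stop("'K' must be a square matrix", call. = FALSE)
  }
  if (any(K < 0)) stop("kernel values must be nonnegative", call. = FALSE)
  v <- rowSums(K)
  if (any(v <= 0)) stop("zero kernel row sum: corrupt kernel input", call. = FALSE)
  P <- K / v
  P_sym <- K / sqrt(outer(v, v))
  structure(
    list(P = P, P_sym = P_sym, v = v, sigma = sigma, base_metric = base),
    class = "transition_matrices"
  )
}

#' Diffusion-map embedding of the random walk
#'
#' Full symmetric eigendecomposition of `P_sym`; eigenpairs are sorted by
#' decreasing `|lambda|` and each eigenvector's sign is fixed so that its
#' largest-magnitude component is positive (distances are sign-invariant, the
#' convention only makes serialized embeddings reproducible).  The diffusion
#' map at time `m` assigns each sample the coordinates
#' `(lambda_1^m phi_1(x), ..., lambda_n^m phi_n(x))`.
#'
#' @param Tm a [transition_matrices()] result.
#' @param m diffusion time: a positive integer number of random-walk steps
#'   (default 50).
#' @return Object of class `diffusion_map`: `values` (eigenvalues), `vectors`
#'   (orthonormal columns), `m`, `v`, `sigma`, `base_metric`, `n`.
#' @export
diffusion_embedding <- function(Tm, m = 50L) {
  stopifnot(inherits(Tm, "transition_matrices"))
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m)) {
    stop("'m' must be a positive integer", call. = FALSE)
  }
  eg <- eigen(Tm$P_sym, symmetric = TRUE)
  if (anyNA(eg$values)) stop("eigendecomposition failed to converge", call. = FALSE)
  ord <- order(-abs(eg$values), seq_along(eg$values))
  vals <- eg$values[ord]
  vecs <- eg$vectors[, ord, drop = FALSE]
  for (j in seq_len(ncol(vecs))) {
    pk <- which.max(abs(vecs[, j]))
    if (vecs[pk, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(
    list(values = vals, vectors = vecs, m = as.integer(m), v = Tm$v,
         sigma = Tm$sigma, base_metric = Tm$base_metric, n = length(vals)),
    class = "diffusion_map"
  )
}

#' @export
print.diffusion_map <- function(x, ...) {
  cat("diffusion_map: n = ", x$n, ", m = ", x$m,
      ", lambda_2 = ", format(x$values[2L], digits = 6), "\n", sep = "")
  invisible(x)
}

#' Diffusion-map coordinates
#'
#' @param embedding a [diffusion_embedding()] result.
#' @param m override the embedding's diffusion time.
#' @return n x n matrix whose row `x` is `Phi_m(x)`.
#' @export
diffusion_coords <- function(embedding, m = embedding$m) {
  stopifnot(inherits(embedding, "diffusion_map"))
  sweep(embedding$vectors, 2L, embedding$values^m, "*")
}

#' Pairwise diffusion distances from an embedding
#'
#' Euclidean distances between diffusion-map coordinates; by the spectral
#' identity these equal the random-walk diffusion distances
#' `d_m^2(x, y) = sum_z (p~^(m)(x, z) - p~^(m)(y, z))^2`.
#'
#' @param embedding a [diffusion_embedding()] result.
#' @param m override the embedding's diffusion time.
#' @return Symmetric matrix with zero diagonal, attribute `kind = "diffusion"`.
#' @export
diffusion_distance_matrix <- function(embedding, m = embedding$m) {
  co <- diffusion_coords(embedding, m)
  D <- as.matrix(stats::dist(co))
  dimnames(D) <- NULL
  attr(D, "kind") <- "diffusion"
  D
}
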