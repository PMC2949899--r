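# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Sum three nonnegative vectors elementwise in ascending sorted order.
# Addition order is then invariant under any permutation of the three inputs,
# which makes squared lattice distances bit-identical under axis permutations
# and sign flips (90-degree grid rotations).  Inputs that are exact integers
# below 2^53 are summed exactly.
sum3_sorted <- function(a, b, c) {
  m1 <- pmin(a, b)
  M1 <- pmax(a, b)
  m2 <- pmin(M1, c)
  M2 <- pmax(M1, c)
  lo <- pmin(m1, m2)
  mid <- pmax(m1, m2)
  (lo + mid) + M2
}

# Squared Euclidean distances (in lattice-index units) from each row of the
# integer matrix `pts` to the single point `q`, permutation-invariant.
sqdist_to_point <- function(pts, q) {
  sum3_sorted(
    (pts[, 1L] - q[1L])^2,
    (pts[, 2L] - q[2L])^2,
    (pts[, 3L] - q[3L])^2
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
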