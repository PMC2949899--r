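#' Histogram shape descriptor from a pairwise distance matrix
#'
#' Collects the n(n-1)/2 unordered off-diagonal values of a pairwise distance
#' matrix, min-max rescales them to [0, 1], counts them into `n_bin`
#' equal-width bins (half-open on the right except the last bin, so the value
#' 1 is counted exactly once) and normalizes the counts to frequencies summing
#' to 1.  Applied to diffusion distances this is the DDSD; applied to inner or
#' Euclidean distances it gives the ID and ED baseline descriptors.  The
#' min-max normalization makes the descriptor invariant to any positive
#' rescaling of the distances, hence to rigid motion and global scale.
#'
#' If all distances are identical (max = min, e.g. n = 2) the whole mass is
#' placed in the first bin: such a histogram carries no shape information and
#' any fixed placement is equivalent, but a defined answer beats an error.
#'
#' @param D symmetric pairwise distance matrix (n >= 2).
#' @param n_bin number of histogram bins (>= 2, default 128).
#' @param meta optional named list stored with the descriptor (e.g. n, m,
#'   sigma); the distance kind is recorded automatically.
#' @return Object of class `shape_descriptor`: `bins` (frequencies), `n_bin`,
#'   `range` (raw min/max before normalization), `n_values`, `meta`.
#' @export
build_descriptor <- function(D, n_bin = 128L, meta = list()) {
  if (!is.matrix(D) || nrow(D) != ncol(D) || nrow(D) < 2L) {
    stop("'D' must be a square matrix of order >= 2", call. = FALSE)
  }
  n_bin <- as.integer(n_bin)
  if (is.na(n_bin) || n_bin < 2L) stop("'n_bin' must be >= 2", call. = FALSE)
  vals <- D[upper.tri(D)]
  rng <- range(vals)
  if (rng[2L] > rng[1L]) {
    z <- (vals - rng[1L]) / (rng[2L] - rng[1L])
    bin <- pmin(floor(z * n_bin) + 1L, n_bin)
    counts <- tabulate(bin, nbins = n_bin)
  } else {
    counts <- c(length(vals), rep(0L, n_bin - 1L))
  }
  meta$kind <- dist_kind(D)
  meta$n <- meta$n %||% nrow(D)
  structure(
    list(bins = counts / length(vals), n_bin = n_bin, range = rng,
         n_values = length(vals), meta = meta),
    class = "shape_descriptor"
  )
}

#' @export
print.shape_descriptor <- function(x, ...) {
  cat("shape_descriptor (", x$meta$kind %||% "unknown", "): ",
      x$n_bin, " bins from ", x$n_values, " pairwise distances\n", sep = "")
  invisible(x)
}

#' Dissimilarity between two histogram descriptors
#'
#' @param a,b `shape_descriptor` objects with equal bin counts.
#' @param metric `"L1"` (Manhattan), `"L2"` (Euclidean), `"chi2"`
#'   (`sum (a-b)^2/(a+b)` over bins with positive mass), or
#'   `"bhattacharyya"` (`1 - sum sqrt(a b)`).
#' @return Single nonnegative dissimilarity; 0 for identical histograms.
#' @export
compare_descriptors <- function(a, b,
                                metric = c("L1", "L2", "chi2", "bhattacharyya")) {
  stopifnot(inherits(a, "shape_descriptor"), inherits(b, "shape_descriptor"))
  metric <- match.arg(metric)
  if (a$n_bin != b$n_bin) {
    stop("descriptors have different bin counts (", a$n_bin, " vs ",
         b$n_bin, ")", call. = FALSE)
  }
  p <- a$bins
  q <- b$bins
  switch(metric,
    L1 = sum(abs(p - q)),
    L2 = sqrt(sum((p - q)^2)),
    chi2 = {
      s <- p + q
      use <- s > 0
      sum((p[use] - q[use])^2 / s[use])
    },
    bhattacharyya = max(0, 1 - sum(sqrt(p * q)))
  )
}

#' Piecewise-linear view of a descriptor for plotting
#'
#' @param descriptor a `shape_descriptor`.
#' @return data.frame with bin-centre `x` (normalized distance) and
#'   frequency `y`.
#' @export
descriptor_pwl <- function(descriptor) {
  stopifnot(inherits(descriptor, "shape_descriptor"))
  data.frame(
    x = (seq_len(descriptor$n_bin) - 0.5) / descriptor$n_bin,
    y = descriptor$bins
  )
}

#' @export
#' @importFrom graphics plot
plot.shape_descriptor <- function(x, ..., type = "l",
                                  xlab = "normalized pairwise distance",
                                  ylab = "frequency") {
  pw <- descriptor_pwl(x)
  plot(pw$x, pw$y, type = type, xlab = xlab, ylab = ylab, ...)
  invisible(x)
}

#' Serialize descriptors as JSON
#'
#' The file stores `bins`, `n_bin`, `range`, `n_values` and `meta`; it is
#' human-diffable and round-trips exactly.
#'
#' @param descriptor a `shape_descriptor`.
#' @param path JSON file path.
#' @return `write_descriptor` returns `path` invisibly; `read_descriptor`
#'   returns the `shape_descriptor`.
#' @export
write_descriptor <- function(descriptor, path) {
  stopifnot(inherits(descriptor, "shape_descriptor"))
  jsonlite::write_json(unclass(descriptor), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_descriptor
#' @export
read_descriptor <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(bins = as.numeric(x$bins), n_bin = as.integer(x$n_bin),
         range = as.numeric(x$range), n_values = as.integer(x$n_values),
         meta = as.list(x$meta)),
    class = "shape_descriptor"
  )
}
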