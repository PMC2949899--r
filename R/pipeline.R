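#' Full descriptor pipeline for a voxel model
#'
#' Runs the four descriptor stages on a volumetric model: (1) uniform landmark
#' sampling on the boundary surface, (2) inner distances between all landmark
#' pairs by Dijkstra on the object-voxel graph, (3) diffusion distances via
#' the Gaussian kernel on inner distances, Markov normalization and the
#' diffusion-map embedding at time `m`, (4) the normalized `n_bin`-bin
#' histogram of all pairwise distances.  `ddsd()` returns just the descriptor;
#' `ddsd_pipeline()` also returns every intermediate object.
#'
#' @param model a [voxel_model()].
#' @param n number of landmark points (default 500).
#' @param m diffusion time in random-walk steps (default 50).
#' @param n_bin histogram bins (default 128).
#' @param sigma Gaussian kernel width, or `"auto"` for the mean pairwise
#'   inner distance (default).
#' @param seed sampling seed (default 1).
#' @param distance which pairwise distance feeds the histogram:
#'   `"diffusion"` (the DDSD, default), `"inner"` (ID baseline) or
#'   `"euclidean"` (ED baseline).
#' @param sampling `"lloyd"` (uniform, default) or `"random"`.
#' @param graph optionally a prebuilt [build_voxel_graph()] for `model`.
#' @return `ddsd()`: a [build_descriptor()] object.  `ddsd_pipeline()`: a list
#'   with `model`, `boundary`, `samples`, `graph`, `D_inner`, `D_euclidean`,
#'   `kernel`, `embedding`, `D` (histogrammed matrix) and `descriptor`.
#' @examples
#' ball <- make_ball(radius = 8, dims = 24)
#' d <- ddsd(ball, n = 60, m = 50, n_bin = 32, seed = 7)
#' sum(d$bins)
#' @export
ddsd <- function(model, n = 500L, m = 50L, n_bin = 128L, sigma = "auto",
                 seed = 1L, distance = c("diffusion", "inner", "euclidean"),
                 sampling = c("lloyd", "random"), graph = NULL) {
  ddsd_pipeline(model, n = n, m = m, n_bin = n_bin, sigma = sigma,
                seed = seed, distance = distance, sampling = sampling,
                graph = graph)$descriptor
}

#' @rdname ddsd
#' @export
ddsd_pipeline <- function(model, n = 500L, m = 50L, n_bin = 128L,
                          sigma = "auto", seed = 1L,
                          distance = c("diffusion", "inner", "euclidean"),
                          sampling = c("lloyd", "random"), graph = NULL) {
  stopifnot(inherits(model, "voxel_model"))
  distance <- match.arg(distance)
  sampling <- match.arg(sampling)
  boundary <- extract_boundary(model)
  samples <- switch(sampling,
    lloyd = sample_uniform(boundary, n, seed),
    random = sample_random(boundary, n, seed)
  )
  out <- list(model = model, boundary = boundary, samples = samples)
  out$D_euclidean <- euclidean_distance_matrix(samples)
  if (distance != "euclidean") {
    out$graph <- graph %||% build_voxel_graph(model)
    out$D_inner <- inner_distance_matrix(out$graph, samples)
  }
  if (distance == "diffusion") {
    out$kernel <- gaussian_kernel(out$D_inner, sigma = sigma)
    out$embedding <- diffusion_embedding(transition_matrices(out$kernel), m = m)
    out$D <- diffusion_distance_matrix(out$embedding)
  } else {
    out$D <- switch(distance, inner = out$D_inner, euclidean = out$D_euclidean)
  }
  meta <- list(n = samples$n, m = if (distance == "diffusion") as.integer(m),
               sigma = if (distance == "diffusion") out$kernel$sigma,
               seed = samples$seed, sampling = sampling)
  out$descriptor <- build_descriptor(out$D, n_bin = n_bin, meta = meta)
  out
}
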