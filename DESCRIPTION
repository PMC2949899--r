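Package: ddsd
Title: Diffusion Distance Shape Descriptors for Flexible Molecular Shape Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compute and compare diffusion distance shape descriptors (DDSD) of
    molecular shapes represented as binary voxel models. Molecular surfaces
    (closed triangle meshes, PDB atom lists as union-of-spheres, or raw voxel
    grids) are rasterized onto a uniform lattice; landmark points are sampled
    uniformly on the boundary with Lloyd's algorithm; inner distances (shortest
    paths through the molecular volume) between all landmark pairs are computed
    by Dijkstra's algorithm on the 26-connected voxel graph; a Gaussian kernel
    on inner distances drives a Markov random walk whose spectral decomposition
    yields diffusion maps and diffusion distances; the normalized histogram of
    all pairwise diffusion distances is the descriptor. Includes histogram
    similarity metrics (L1, L2, chi-squared, Bhattacharyya), a retrieval
    harness with precision-recall, E-measure and F-measure statistics, and
    generators of articulated synthetic voxel shapes (conformer series that
    undergo self-contact topology changes) for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
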