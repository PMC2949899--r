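# ddsd — diffusion distance shape descriptors for flexible molecules

Many molecules are flexible: hinge and domain motions deform their surface so
strongly that rigid-body shape comparison mistakes conformers of the same
molecule for different molecules. Shortest-path ("inner") distances through
the molecular volume are robust to articulation, but they break down at
*topological changes* — when two previously separate surface regions touch,
a shortcut appears and every shortest path re-routes through it.

`ddsd` implements the **diffusion distance shape descriptor (DDSD)** for this
setting. Instead of the single shortest path, it measures an *average over
all paths* of an m-step random walk whose single-step affinities come from a
Gaussian kernel on inner distances, so one new shortcut is averaged against
every other route and perturbs the metric only mildly. The package is aimed
at structural bioinformatics users who need alignment-free retrieval of
conformers from shape databases, and at method developers who want a fully
testable, self-contained implementation with synthetic morph benchmarks.

## Method

For a volumetric model of the molecule (binary occupancy on a uniform
lattice; an object voxel is a boundary voxel when one of its 26 neighbours is
background):

1. **Sampling.** Choose n landmark points uniformly on the boundary surface
   with Lloyd's k-means (default n = 500).
2. **Inner distances.** d_I(q_i, q_j) = length of the shortest path between
   landmarks through the object voxels (Dijkstra on the 26-connected voxel
   graph, edge weights s, s√2, s√3 for lattice step s).
3. **Diffusion distances.** Build the kernel
   k(x, y) = exp(−d_I²(x, y)/σ²), with σ the mean pairwise inner distance;
   normalize to the random walk p(x, y) = k(x, y)/v(x), v(x) = Σ_y k(x, y),
   and its symmetric conjugate p̃(x, y) = k(x, y)/√(v(x)v(y)).
   Eigendecomposition p̃ = Σ λ_i φ_i φ_iᵀ gives the diffusion map
   Φ_m(x) = (λ_1^m φ_1(x), λ_2^m φ_2(x), …); the diffusion distance at time
   m (default 50) is d_m(x, y) = ‖Φ_m(x) − Φ_m(y)‖, which equals the
   random-walk definition d_m²(x, y) = Σ_z (p̃^(m)(x, z) − p̃^(m)(y, z))².
4. **Descriptor.** The n(n−1)/2 pairwise diffusion distances are min-max
   normalized and histogrammed into 128 equal bins; frequencies sum to 1.
   Descriptors are compared with L1/L2/χ²/Bhattacharyya histogram metrics.

Inputs can be closed triangle meshes (OFF/PLY), PDB atom records rasterized
as a union of van der Waals spheres, or raw voxel grids. A retrieval harness
(precision–recall curves, E-measure, F-measure) and generators of articulated
synthetic conformer series with controlled self-contact events round out the
package.

## Worked example

A tube of fixed arc length is bent until its free ends touch and it closes
into a ring — a pure topology change:

```r
library(ddsd)
tube_open <- make_bent_tube(length = 40, thickness = 3, bend_angle = 240, dims = 48)
tube_ring <- make_bent_tube(length = 40, thickness = 3, bend_angle = 350, dims = 48)
tube_open
#> voxel_model: 48 x 48 x 48 lattice, spacing 0.545622, 7448 object voxels

tip_inner_distance(tube_open)$distance   # 35.5  (through the whole tube)
tip_inner_distance(tube_ring)$distance   #  1.2  (shortcut across the contact)

dd_open <- ddsd(tube_open, n = 250, m = 50, seed = 1)
dd_ring <- ddsd(tube_ring, n = 250, m = 50, seed = 1)
dd_open
#> shape_descriptor (diffusion): 128 bins from 31125 pairwise distances

id_open <- ddsd(tube_open, n = 250, seed = 1, distance = "inner")
id_ring <- ddsd(tube_ring, n = 250, seed = 1, distance = "inner")

compare_descriptors(dd_open, dd_ring, "L1")  # 0.19
compare_descriptors(id_open, id_ring, "L1")  # 0.41
```

The tip-to-tip inner distance collapses from 35.5 to 1.2 length units at
contact, and the inner-distance histogram moves twice as far (L1 = 0.41) as
the diffusion-distance histogram (L1 = 0.19): the averaged-path metric
absorbs the shortcut.

A thin CLI wrapping the same functions is installed at
`inst/cli/ddsd.R` (`voxelize`, `describe`, `compare`, `synth`, `benchmark`).

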