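---
title: "Canopy fingerprints from TLS point clouds: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canopy fingerprints from TLS point clouds: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopyprint)
```

## The problem

Terrestrial laser scanners (TLS) capture row-crop canopies — here, the
motivating system is soybean grown in hill plots at 0.76 m spacing — as
dense 3D point clouds. Conventional post-processing compresses each canopy
into a handful of whole-plant numbers (height, volume, surface area) that
ignore how shape varies with height; latent-feature alternatives (PCA,
neural embeddings) capture that variation but are hard to interpret.
`canopyprint` implements a middle ground: the **canopy fingerprint**, a
vector of per-slice geometric features, each slice normalized by the
canopy's center slice. Fingerprints are interpretable (every entry is a
named geometric ratio at a named height), comparable across canopies of
different absolute size, and searchable by plain Euclidean distance.

The package covers the whole path from raw multi-view scans to a queryable
fingerprint database: density homogenization, statistical denoising,
reference-marker detection and block cropping, sphere-target rigid
registration with optional ICP refinement, ground-plane fitting and
per-plot segmentation, 3D/2D trait extraction, and fingerprint
generation, query, and clustering. A seeded synthetic-scene generator
stands in for field data so every stage is testable end to end.

## The fingerprint model

A canopy cloud is cut along z into $2n+1$ equal-height slices (so the
count is always odd and a center slice exists; $n$ is tunable, with $n=1$
giving 3 sub-canopies and $n=4$ giving 9). For each slice a **signature**
of geometric features is computed — by default the projected 2D outline
features (area, aspect ratio, circularity, roundness, convex area,
solidity) plus the slice hull volume. Writing $s_{ij}$ for feature $j$ of
slice $i$ and $c = n$ for the center index (0-based), the fingerprint is

$$ f_{ij} = s_{ij} / s_{cj}, $$

flattened slice-major from bottom to top. The center block is identically
1 by construction. Because every default feature is homogeneous under
uniform scaling, center normalization cancels absolute size: the
fingerprint describes *shape profile*, not magnitude. It is exactly
invariant under translation, invariant under rotation about z up to
outline discretization (about 1% in practice), and deliberately **not**
invariant under tilt — a lodged plant fingerprints differently from an
upright one, which is informative rather than a defect.

The 2D outline descriptors follow the standard image-analysis
definitions:

* circularity $= 4\pi A / P^2$,
* roundness $= 4A / (\pi\,\mathrm{MajorAxis}^2)$,
* solidity $= A / A_\mathrm{convex}$,
* aspect ratio $=$ major / minor axis of the best-fit ellipse.

`MajorAxis` is the **full** major-axis length of the ellipse whose region
second moments match the polygon's; this convention is self-consistent
(a circle scores exactly 1 on circularity, roundness, and solidity, which
the tests verify on a regular 1000-gon). The ellipse is fitted from the
polygon-*region* moments, not the vertex scatter, so vertex density
cannot bias the axes.

## Pipeline stages and their parameters

**Voxel downsampling** (`voxelDownsample`, default 5 mm). TLS point
density varies strongly with range; a regular voxel grid in which every
occupied voxel is replaced by the mean of its member points (coordinates
and colors alike) restores uniform density. Voxel indices are
`floor(x / voxel)` per axis with boundary points assigned to the
higher-index voxel — a deterministic convention.

**Statistical outlier removal** (`removeStatisticalOutliers`, defaults
k = 24, α = 0.075). Phase-shift LiDAR generates spurious "mixed" points
at object edges. Each point's mean distance to its k nearest neighbors
(the point itself excluded — including it would bias every average toward
zero) is compared with the cloud-wide threshold $\mu + \alpha\sigma$;
smaller α removes more aggressively. The defaults are the values selected
by monitoring canopy-height stability over a 5 × 8 parameter sweep
(`sweepNoiseParams` reproduces the protocol); the threshold is recomputed
for every input cloud, never cached.

**Marker detection and block cropping** (`detectColorMarkers`,
`cropBlock`). Painted reference spheres are found by color class — white
means all normalized RGB channels ≥ 0.85, yellow R,G ≥ 0.75 with
B ≤ 0.4, red R ≥ 0.75 with G,B ≤ 0.4 — combined with a z > 1 m
constraint that excludes white objects near the ground such as plot-stake
labels. The source protocol gives no numeric color thresholds; these
defaults separate painted targets from foliage in the synthetic scenes
and are configurable. Survivors are clustered by fixed-radius connected
components and each cluster centroid is a marker center. The block is
cropped to the closed quadrilateral spanned by the four white corner
markers.

**Registration** (`estimateRigidTransform`, `icpRefine`,
`registerViews`). Marker-center correspondences feed a closed-form
orthogonal Procrustes fit (SVD of the cross-covariance with determinant
correction, so reflections are impossible); it is exact to machine
precision on clean correspondences. Four views are merged by chaining
three registrations into the first view's frame, then voxel-downsampling
once more to collapse duplicated points. The quality gate is the paper of
record for this protocol: per-step marker RMSE below 0.01 m. Because a
library cannot reproduce interactive sphere pairing, `canopyprint`
matches markers automatically by their sorted vectors of pairwise
distances — a rigid-motion invariant — requiring at least three markers
with distinct signatures; explicit pairings are also accepted. ICP
(point-to-point, 0.05 m correspondence gate) is an optional refinement;
an iteration is accepted only if it lowers the gated RMSE, so the
reported error never increases.

**Plot segmentation** (`fitPlane`, `extractGroundBand`, `segmentPlots`).
A least-squares plane $z = ax + by + c$ fitted to the whole block passes
through the mid-canopy because the fit balances canopy and ground mass;
points above it are canopy tops, which connected components split into
plots whose mean (x, y) is the plot center. Around each center a square
annulus (inner square side 0.1 m, band width 0.1 m — both knobs) supplies
the "faithful ground" points for the per-plot ground plane; the canopy is
then every point assigned to that plot (nearest center in the x–y plane,
a deterministic choice the source protocol leaves open) lying above its
plane. Three robustness refinements are the package's own: (1) only band
points within 0.05 m of the band's lowest z enter the plane fit, since a
wide canopy can overhang the band — in particular, the band's outer
*square* reaches inside a circular canopy footprint at its diagonals;
(2) the fit is trimmed (residuals > 2.5 × RMSE dropped, refit, twice);
(3) canopy membership requires clearing the plane by 3 × the plane-fit
RMSE, so surface roughness does not leak ground points into the canopy —
the clearance is zero for exactly planar ground. A top cluster must also
rise ≥ 0.05 m above the block plane, which suppresses phantom "canopies"
assembled from roughness residuals on canopy-free blocks.

**Traits** (`canopyHeight`, `canopyMesh`, `meshTraits`,
`projectOutline`, `outlineTraits`). Height is the mean z of the top 3% of
points minus the minimum z (count `ceiling(0.03 N)`, at least one point;
the rounding is unstated in the protocol and fixed here). Averaging a top
fraction is robust to residual high outliers but reads low on sharply
pointed shapes — on an ideal cone the top-3% mean sits ≈ 9% of the height
below the apex, which is a property of the trait definition, not of the
implementation; the tests therefore validate height recovery on
cylinders, whose top-3% height matches the solid height. Volume and
surface area come from a watertight triangular mesh: the default is the
3D convex hull; `slice_hull` stacks per-slab 2D convex outlines into a
lofted watertight solid and is tighter wherever the silhouette narrows
and widens with height (an hourglass test verifies this). Mesh volume
uses signed-tetrahedron summation, area the triangle-area sum.

**Fingerprints, query, clustering** (`computeFingerprint`,
`queryNearest`, `ideotypeFingerprint`, `clusterFingerprints`). Queries
rank database entries by Euclidean distance on the full vectors (an
optional per-entry weight vector defaults to ones); ties break
lexicographically by canopy id. Ideotype queries are built analytically:
a cylinder is all ones; a cone's profile follows the closed forms of its
equal-height frusta (projected areas scale with the squared slice base
radius — at $n=1$ the area profile is $(2.25, 1, 0.25)$ bottom to top);
an inverted cone reverses the slice order. Clustering is seeded k-means
on the raw fingerprint vectors — the source material does not name an
algorithm, and k-means is deterministic under a fixed seed; PCA supplies
a 2D embedding for display only and never feeds the clustering. Database
CSVs carry a JSON sidecar recording n, the feature order, and the outline
mode, so fingerprints are never compared across incompatible layouts.

## The synthetic test bed

`generateCanopy` samples parametric solids (cone, inverted cone,
cylinder, ellipsoid, hemisphere) on their surface or volume. Cones and
cylinders are sampled by inverse-CDF in z so density is uniform per
surface/volume element — naive uniform-z sampling would bias fingerprint
slice counts. `generateFieldScene` assembles a labeled hill-plot block:
a flat ground patch with Gaussian roughness (default σ = 5 mm) sampled
at ≈ 15 mm pitch with jittered grid positions, cone canopies (radius
0.25 m, height 0.8 m, 3000 surface points each) on the 0.76 m grid,
white corner spheres and six colored in-block spheres of 0.127 m diameter
centered at the 1.52 m dowel-top height — the marker geometry of the
emulated field protocol. Component densities are deliberately comparable
(≈ 15 mm spacing everywhere): the µ+ασ denoiser judges points against the
cloud-wide distance distribution, and a component sampled much more
sparsely than the rest would be wrongly eliminated wholesale, which is a
property of the filter worth knowing about rather than a bug.
`simulateViews` applies known rigid poses, removes an exact seeded
fraction of points, and adds isotropic Gaussian noise (default σ = 2 mm,
the instrument's point-spacing scale at a 10 m range).

What the generator does **not** emulate: occlusion (no ray casting —
dropout is random, so self- and neighbor-shadowing are absent), wind
motion, range-dependent density, beam divergence, or phase-shift edge
artifacts (the denoiser is exercised against generic Gaussian
displacement and implanted far outliers instead). Passing tests therefore
demonstrate algorithmic correctness under idealized sampling, not
robustness to every field pathology.

## Numerical choices

* **Convex hull.** The 3D hull is an incremental construction (compiled):
  each point's most-violated face seeds a breadth-first search across
  face adjacency, so the removed region is edge-connected and its horizon
  is a single closed loop. Surface-sampled solids of revolution are
  developable and riddled with nearly coplanar quadruples that no
  visibility epsilon classifies consistently; the inputs are therefore
  joggled by a deterministic relative jitter of $10^{-7}$ before
  insertion. The induced vertex error is orders of magnitude below the
  millimeter noise of TLS data, and hull volumes converge to analytic
  solids within 0.1% at $2 \times 10^4$ surface samples.
* **Slice assignment** uses half-open intervals `[low, high)` with a
  closed top slice, so boundary points are deterministic.
* **Center-zero features.** If a center-slice feature is 0 while another
  slice's value is nonzero, that feature column is kept raw and flagged
  in the fingerprint's metadata — silent division is never performed. A
  fully degenerate center slice is an error advising a smaller n.
* **Z-score outlier flagging** uses the population standard deviation;
  at realistic sample sizes the difference from the sample deviation is
  negligible, and the choice is fixed for determinism.
* **Empty inputs** are defined everywhere: empty clouds read and write
  valid files, empty slices produce flagged zero signatures, an empty
  ground band falls back to the block-level plane with a warning flag on
  the affected segment.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
that every stochastic check is comfortably inside its tolerance: field
scenes of 2 × 2 to 3 × 3 hills (≈ 3–4 × 10⁴ points), four simulated views
with 20% dropout and 2 mm noise, hull-convergence checks at 2 × 10⁴
samples, oracle cross-checks on clouds of up to 500 points across 20
seeds, and a 20-canopy retrieval database. All randomness flows through
explicit seeds; two runs with equal inputs are byte-identical.

## Known limitations

* Convex hulls (and convex outlines) overestimate concave canopies, and
  a single stray point can inflate them noticeably; `slice_hull` and the
  alpha outline mode mitigate but do not remove this.
* The top-3% height systematically underestimates sharply pointed
  canopies (see above).
* Overlapping canopies are not separated: nearest-center assignment
  slices the contact region by the perpendicular bisector, and occlusion
  failures of the kind the emulated protocol reports would pass through
  unchanged.
* Terrain is modeled as locally planar; strongly curved ground would
  need a spline or DEM model, which is out of scope.
* Fingerprints are sensitive to tilt by design; comparing lodged and
  upright plants requires either uprighting the clouds first or treating
  the difference as signal.
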