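---
title: "Methods: 3D dendritic spine morphometry, clustering, and group statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D dendritic spine morphometry, clustering, and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`spinemorph` quantifies the 3D shape of dendritic spines reconstructed from
confocal image stacks and tests how spine populations differ between
experimental groups. This vignette is the package's account of the models
and procedures it implements, the tunable parameters and why their defaults
are what they are, and the numerical and design decisions a careful reader
should know about.

## From image stack to surface mesh

**Input.** A single-channel multi-page TIFF, already deconvolved, with
anisotropic voxel spacing given as `(z, y, x)` in µm. The defaults,
`(0.24, 0.05, 0.05)`, correspond to confocal acquisition at 0.05 µm pixels
and 0.35 µm optical sectioning whose z step has been corrected for
spherical aberration. The correction itself is outside the package's
scope: the z spacing is a single configurable number, and users who know
their own correction factor supply their own spacing.

**Black-pixel artifact repair.** Segmented confocal slices occasionally
contain isolated zero-valued pixels. `fix_black_pixels()` works per 2D
slice: a pixel with value 0 whose eight in-plane neighbors are all
positive is replaced by the mean of those eight neighbors. The rule is
applied in one pass over the original values, so repairs never cascade,
and a zero pixel with any zero or missing neighbor is left untouched. The
neighborhood is in-plane because the artifact is an in-plane phenomenon of
the slice-wise acquisition.

**Segmentation.** `segment_acwe()` implements morphological active
contours without edges (Chan–Vese in its morphological formulation). Each
iteration attracts the region toward intensity homogeneity — a voxel joins
the foreground where
$\lambda_1 (I - c_1)^2 < \lambda_2 (I - c_0)^2$ along the current front,
with $c_1, c_0$ the mean intensities inside and outside — and then applies
`mu_smooth` passes of the morphological curvature operator (alternating
sup-of-erosions and inf-of-dilations over nine planar 3×3 structuring
elements). Defaults are $\mu = 1$, $\lambda_1 = 1$, $\lambda_2 = 9$, 100
iterations: background is weighted heavily because spines are sparse
bright objects on a dark background. The iteration count is a fixed
budget, not a convergence test; the morphological formulation reaches a
stable front well within it on stacks of this kind.

Two details are deliberate choices. The initial level set is the Otsu
threshold of the slice-wise min–max normalized stack (per-slice
normalization keeps dim z-planes contributing; min–max makes the
initialization — and hence the whole segmentation — invariant to global
affine intensity rescaling). A checkerboard initialization is available as
the conventional alternative. A constant stack returns an empty mask with
a warning flag rather than an error, so batch runs skip blank fields
gracefully.

The implementation was verified voxel-for-voxel against an independent
reference implementation of the same algorithm. Two practical limits are
worth knowing: with $\mu = 1$ the curvature operator maintains a
voxel-scale equilibrium at the boundary, so even a noiseless binary input
is recovered only up to its surface voxel layer; and structures thinner
than ~3 voxels along any axis (a thin spine neck at 0.24 µm z spacing) can
be erased by the smoothing — the same reason thin protrusions are
notoriously hard to reconstruct from fixed-tissue confocal data.

**Surface extraction.** `mesh_from_volume()` extracts the 0.5 isosurface
of the binary mask with physical spacing applied. Rather than the
256-case table formulation of marching cubes, the package uses the
tetrahedral-decomposition variant: each grid cell is split into six
tetrahedra (Kuhn subdivision, face-compatible between neighboring cells)
and the isosurface is triangulated within each tetrahedron. The variant
is exactly implementable without external case tables, and on a padded
mask it is watertight and consistently outward-oriented by construction.
Cut vertices on shared cell edges are welded so the result is an indexed
mesh. Masks whose foreground touches the grid boundary are padded with
one background layer (with a warning) so the surface always closes.

One systematic effect of extracting an isosurface from a *binary* mask is
that vertices sit at edge midpoints, producing a faceted staircase whose
**enclosed volume is accurate (sub-percent on a 1 µm ball at 0.05 µm
voxels) but whose raw area overestimates the smooth surface**. Mesh-derived
volumes can therefore be compared across conditions directly, while
surface areas are comparable between spines reconstructed the same way but
are not estimates of the true smooth area. The analytic accuracy suite in
the tests pins both behaviors.

## The mesh optimization and repair loop

`repair_mesh()` runs a fixed sequence: bounding box and target edge
length from the box diagonal (diagonal/100 at `normal` detail,
diagonal/50 at `reduced`; the divisors are configurable and recorded in
the report); removal of collinear (zero-area) triangles; removal of
isolated vertices; elimination of self-intersecting faces; removal of
duplicated faces; isolated vertices again; an outer-hull-volume integrity
probe; removal of triangles with an interior angle above 179°; duplicated
faces and duplicated vertices once more; and a final integrity
assessment (edge-manifoldness plus a computable convex hull). If the
assessment fails, the loop restarts once at reduced detail, then raises a
repair-failure error.

Numerical decisions: self-intersection uses a strict-interior
segment–triangle test (Möller–Trumbore) with barycentric tolerance
10⁻⁹, after bounding-box pruning; faces sharing a vertex are never
flagged, so legitimately adjacent triangles survive. Offending faces are
deleted, not remeshed. The interior-angle test uses exact `acos` on face
angles with a strict `> 179°` comparison. Repair is idempotent: a second
pass reports zero removals of every kind.

## The ten morphometric descriptors

A spine cut from its dendrite has an open rim. The rim vertices have the
fewest edge neighbors in the mesh, and the **spine base center**
$S_{bc}$ is the mean coordinate of all vertices at the mesh-wide minimum
neighbor count. The **gravity center** $G_c$ is the unweighted vertex
centroid; it also serves as the apex of the signed-tetrahedra volume sum
(the two roles are a single point by definition here, since neither is
meaningfully distinguishable for these meshes).

| Feature | Definition | Units |
|---|---|---|
| `L` | mean of the `ceil(0.05 N)` largest vertex-to-$S_{bc}$ distances | µm |
| `S` | $\sum_f \frac{1}{2}\lvert AB \times AC \rvert$ | µm² |
| `V` | $\lvert \sum_f \frac{1}{6} (AB \times AC) \cdot (A - G_c) \rvert$ on the base-capped surface | µm³ |
| `HV` | convex hull volume of the vertex set (Quickhull) | µm³ |
| `HR` | $(HV - V)/V$ | — |
| `AD` | mean vertex-to-$S_{bc}$ distance | µm |
| `CVD` | population SD of those distances, divided by `AD` | — |
| `OA` | mean angle between the $S_{bc}\!\to\!G_c$ axis and each $S_{bc}\!\to\!$vertex vector | rad |
| `MC` | total integral mean curvature (edge-dihedral) / closed surface area | 1/µm |
| `GC` | total angle defect / closed surface area | 1/µm² |

Decisions behind the definitions:

* **5% subset for `L`:** `n = ceil(0.05 N)` with a floor of 1; ties at the
  cutoff are all included, which keeps the value stable under vertex
  reordering.
* **Open-base volume:** the single boundary loop is capped by a triangle
  fan to $S_{bc}$, with winding that continues the surface orientation, so
  the signed sum is independent of the reference point. Meshes with more
  than one boundary loop are rejected rather than silently mis-capped.
* **`CVD` uses the population (divide-by-N) standard deviation**, with the
  mean in the deviation term being `AD` itself.
* **`OA` vectors are normalized before the dot product** (an arccosine
  requires unit arguments), the dot product is clamped to $[-1, 1]$, and
  vertices coincident with $S_{bc}$ are skipped.
* **Curvatures are total-over-total:** total discrete curvature divided by
  total area, not a per-face ratio summed — per-face division by tiny
  areas is numerically unstable. On the base-capped closed surface the
  Gaussian total is the angle-defect sum, which Gauss–Bonnet fixes at
  exactly $4\pi$ for genus 0; this identity is asserted to 10⁻⁶ in the
  tests, independent of tessellation. The reported `S` remains the open
  surface's area; the curvature normalization uses the capped area so the
  identity holds exactly.
* **Convex hulls** come from an in-package Quickhull-style incremental
  construction (no suitable hull library exists in the package's
  dependency environment); it is validated against brute-force facet
  enumeration on small point sets.

These definitions imply exact equivariances — scaling a mesh by $c$
multiplies `L`, `AD` by $c$, `S` by $c^2$, `V`, `HV` by $c^3$, divides
`MC` by $c$ and `GC` by $c^2$, and leaves `HR`, `CVD`, `OA` unchanged;
rigid motions change nothing — which the test suite asserts at 10⁻⁶
relative tolerance.

## Feature pruning, standardization, PCA

`correlation_prune()` computes the Pearson correlation matrix and keeps,
within any set of features pairwise correlated at $|r| \ge 0.9$, only the
highest-priority one. The default priority prefers the descriptors most
widely used in the spine literature — Length over Average Distance,
Surface over Volume and Hull Volume — and on spine data the retained set
is `{L, S, HR, CVD, OA}`. The 0.9 threshold marks the conventional
"very strong" correlation band; it is a parameter, not a constant.

`standardize()` centers and scales to population SD 1 and stores the
parameters for reuse on held-out data. `fit_pca()` keeps three components
by default; the sign of each component is fixed by making its
largest-magnitude loading positive, so loadings and scores are
reproducible across runs and row orders. Scaler and PCA are intended to be
fitted once on the pooled multi-condition dataset, with group comparisons
done downstream in the shared PC space.

## Clustering and cluster-number selection

`fit_kmeans()` is Lloyd's algorithm with k-means++ seeding, 10 restarts
(best within-cluster sum of squares kept), and a fixed default seed of 0.
Cluster identities are made deterministic by relabeling clusters in
ascending centroid PC1 — k-means labels are otherwise arbitrary across
runs, which would make "cluster 3" meaningless between analyses.

`select_k()` scores each candidate `k` (default 3–11) by mean silhouette
width, the Calinski–Harabasz index, and the elbow criterion, with the
elbow knee defined as the inertia point farthest from the chord joining
the first and last points of the curve (the criterion is conventionally
named but rarely given a formula; the chord rule is deterministic and
scale-free in `k`). The consensus is the majority, with ties going to the
silhouette winner.

`kde_shift()` summarizes how one cluster's members drift between two
groups: a Gaussian KDE on (PC1, PC2) per group — Scott's bandwidth,
100×100 grid spanning the pooled member range extended by three
bandwidths, grid renormalized to unit mass — plus the displacement of the
group centroids as the shift vector. At least 10 members per group are
required; below that a KDE map is noise.

## Group statistics

* **Cluster proportions:** the Agresti–Caffo adjusted two-proportion test.
  One success and one failure are added to each group,
  $\tilde p_i = (x_i + 1)/(n_i + 2)$, the difference is tested with a
  normal z statistic, and the companion 95% interval is
  $\Delta \pm 1.96\,\mathrm{se}$. Per-cluster p-values are reported raw by
  default — one test per cluster is how such distributions are
  conventionally reported — with Holm adjustment available. The test's
  type-I error under a simulated null is asserted to lie in
  [0.035, 0.065] in the acceptance suite.
* **Feature comparisons:** classical pooled-variance unpaired t-tests plus
  Cohen's d with the (n−1)-weighted pooled SD; effects below 0.01 are
  labeled very small and below 0.20 small.
* **Pseudo-replication:** `icc_oneway()` computes the one-way
  random-effects ICC(1) from the ANOVA decomposition,
  $(MS_B - MS_W)/(MS_B + (k_0 - 1) MS_W)$ with $k_0$ the
  balanced-equivalent group size. The default grouping factor is the
  mouse; cell-within-mouse is available. ICC(1) with animal grouping is
  the variant that answers "how much of the spine-level variance is
  animal-level" — other ICC variants answer reliability questions this
  analysis does not ask.

## The synthetic spine generator

Because no microscopy data ship with the package, every stage is testable
against `make_spine_mesh()` / `make_population()`. Three idealized
families cover the classical spine types: a hemisphere on an open base
(stubby), a spherical head fused to a cylindrical neck (mushroom), and a
long narrow neck with a small head (thin). Each solid is meshed as a
surface of revolution, open at the base disk like a spine cut from its
dendrite, and carries its exact analytic surface area and volume, so mesh
estimators can be checked for convergence (the tests assert monotone
error decrease over three resolution levels).

Populations draw per-spine size parameters as family base values times
$\exp(\text{mouse} + \text{cell} + \text{residual})$ — log-normal
(multiplicative) effects keep radii positive — with independent residuals
per parameter, plus a small random tilt. Defaults are 0.10 / 0.08 / 0.12
(log scale), sizes chosen to produce within-family coefficients of
variation comparable to the within-cluster spread reported for real
granule-cell spines. `recovery_population()` is the tighter reference
construction for end-to-end recovery checks (five regimes echoing the
cluster archetypes of granule-cell spine data; dispersion 0.05 / 0.04 /
0.06) in which the regimes form compact, well-separated blobs: on it, all
three cluster-number scores select k = 5 and K-means recovers the regime
labels with adjusted Rand index above 0.8. With a single *shared* size
factor instead of independent residuals, families become one-dimensional
filaments in PC space and the Calinski–Harabasz index increases
monotonically in `k` for any construction — a useful reminder that
cluster-number scores answer questions about cluster *shape* as much as
cluster *count*.

`voxelize_and_degrade()` emulates acquisition: parity ray-casting onto an
anisotropic grid, separable Gaussian blur (sigma in µm converted per
axis), additive Gaussian noise clipped at zero, seeded and reproducible.
What it does **not** emulate: photon statistics, depth-dependent
aberration, the dendrite the spine is attached to, neighboring
structures, and deconvolution residues. Passing the round-trip tests
therefore shows the pipeline is internally consistent and accurate on
resolvable geometry; it does not certify performance on real tissue,
where segmentation quality is dominated by the imaging itself.

## Problem sizes and runtime choices

The test and acceptance workloads use mesh resolution level 1–2
(16–32 azimuthal segments, a few hundred to a few thousand vertices per
spine), populations of 200–1000 spines, segmentation volumes of roughly
30–60 voxels per axis, and 10⁴ replicates for the calibration of the
proportion test. These sizes were chosen so the full suite exercises
every stage at meaningful accuracy in minutes on a single core;
all of them scale up linearly if heavier validation is wanted.

## Known limitations

* Surface areas of voxel-derived meshes carry the binary-mask staircase
  bias discussed above; compare like with like.
* Spines whose necks are thinner than ~3 voxels along z at the default
  spacing may not survive segmentation smoothing; they are
  under-represented in any fixed-tissue confocal analysis, this one
  included.
* The base-center definition assumes a single cut hole; meshes with
  multiple boundary loops are rejected rather than guessed at.
* The volume capping assumes the rim is star-shaped around its centroid,
  which holds for dendrite cuts but not for arbitrary holes.
* K-means with PC1-ordered relabeling is deterministic given the seed,
  but cluster *identities* are only comparable between analyses that used
  the same pooled scaler, PCA and seed.
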