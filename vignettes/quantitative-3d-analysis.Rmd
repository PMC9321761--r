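---
title: "Quantitative 3D analysis of porous and multiphase media with voxmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative 3D analysis of porous and multiphase media with voxmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voxmorph)
```

## Scope and data model

voxmorph quantifies the 3D microstructure of porous and multiphase
materials — volcanic rock vesicle networks, granular media, trabecular
bone — from segmented micro-CT volumes.  Three containers carry all data:
`gray_volume` (8/16-bit scalar field), `binary_volume` (object mask) and
`label_volume` (integer components, 0 = background).  Every volume records an
isotropic voxel size in micrometres because all reported quantities carry
physical units.

Conventions used everywhere:

* voxel indices are 0-based in the user-facing API, axis order (x, y, z)
  with z the slice index; the raw on-disk format is headerless little-endian,
  x-fastest, with a JSON sidecar `{nx, ny, nz, bits, voxel_size_um}`.  These
  are declared conventions, not inferences — raw-volume dialects differ
  between tools, so the sidecar makes files self-describing.
* the object phase is 26-connected, the background 6-connected.  This
  complementary pair is used consistently in the Euler characteristic,
  component labelling, watershed flooding and skeletonisation, which is what
  makes the cross-module topology checks (skeleton preserves the Euler number
  of the object) exact rather than approximate.
* filters handle borders by half-sample reflection.  On production-size
  volumes (hundreds of voxels per edge) the border contribution is
  negligible; on the small test volumes it is not, which is why the choice is
  fixed and the brute-force test oracles implement the same rule.

## Filtering and segmentation

`median_filter_3d` is an exact cubic-window median (default width 3 voxels).
`otsu_threshold` maximises the between-class variance of the full-volume
histogram at native bit depth (256 or 65536 bins, no rebinning) by exhaustive
search.  When empty bins separate the classes the maximiser is a plateau; the
reported threshold is the midpoint of the first maximal plateau, so a
noiseless bimodal volume is cut midway between its modes.  Because pores can
be darker or brighter than the matrix depending on modality and contrast
agent, polarity is a flag (default: object = above threshold), not a
hard-coded choice.

`kmeans_segment` runs Lloyd iterations on the scalar gray values, weighted by
the level histogram.  Initialisation is deterministic — centroids at evenly
spaced quantiles of the gray distribution — which in one dimension is robust
and makes results bit-reproducible without any seed; the `seed` argument is
retained only for interface stability.  Classes are relabelled by ascending
centroid and an equidistant voxel goes to the lower-centroid class.  The
within-class sum of squares is checked in the tests against an exact
dynamic-programming oracle (optimal 1-D clusters are contiguous in sorted
order), a property specific to scalar data.

## Morphology and the separation pipeline

Erosion and dilation use cube or ball structuring elements of odd width;
opening and closing are their idempotent compositions.  The distance
transform is the two-pass (3, 4, 5) chamfer, divided by 3, approximating
Euclidean distance to the nearest in-volume background voxel within the
metric bounds [0.943, 1.106]; the weights are the standard integer choice and
the tests verify the bounds against an all-pairs Euclidean search.

Touching objects are separated by the classical chain: distance transform,
negation (catchment formulation), `h_minima`, then `watershed`.  The
H-minima transform is morphological reconstruction by erosion of `f` from
`f + h`; it removes regional minima shallower than `h` and raises surviving
minima by at most `h`.  A constant field therefore stays flat (uniformly
raised by `h`), which is the fixed-point of the reconstruction rather than a
special case.  The watershed is Meyer-style priority flooding seeded at the
regional minima (plateau-aware, 26-connected); seeds are numbered in linear
voxel index order and ties in relief value break by queue insertion order, so
the labelling is deterministic.  Ridge voxels join the first-flooding basin:
the labels partition the mask, which downstream blob counting requires.

`h` is the one tunable that matters in this pipeline: it is a depth in
voxel-distance units, and suppresses spurious minima caused by surface
roughness of the distance ridge.  Values of 2-4 voxels separate
substantially overlapping spheres; an `h` exceeding the deepest minimum
merges each connected component into a single object.

## Basic analysis: Minkowski functionals and fabric

All three scalar field estimators are linear functionals of the local
2x2x2 voxel configuration statistics:

* **Euler characteristic** — exact count over the closed cubical complex,
  chi = V - E + F - C, realising the 26/6 convention (ball 1, torus 0,
  hollow shell 2).  This is an integer invariant, not an estimate, and is
  additive over disjoint parts.
* **surface area** — discrete Crofton quadrature: boundary crossings are
  counted along the 13 lattice directions of the local cell and combined
  with the Ohser-Mucklich spherical weights (0.045778 per axis direction,
  0.036981 per face diagonal, 0.035196 per space diagonal); stereologically
  S_V = 2 <I_L>.  On a digitised sphere of radius 12 the error is about 4%;
  for strongly aligned plate structures the 13-direction quadrature biases
  the estimate several percent low, which propagates into the plate-model
  thickness below.
* **integral of mean curvature** — M = 2 pi times the average over the three
  axis-aligned section stacks of the total 2D Euler characteristic of the
  sections (M_V = 2 pi times the section Euler density).  Exact for convex
  bodies up to digitisation of the section count.

Counting is minus-sampled (only cells fully inside the VOI), unbiased for
stationary structures; specific values divide by the VOI volume in mm^3.

Fabric anisotropy uses the mean-intercept-length method: test lines at
`line_spacing` voxels (default 2) are traced along `n_directions`
quasi-uniform directions (default 512, spherical Fibonacci lattice; the
`seed` randomly rotates the lattice, which is how sampling stability can be
assessed).  MIL(w) = total sampled line length / number of
object-background crossings; the fabric matrix H solves
1/MIL(w)^2 = w' H w by least squares and the MIL ellipsoid semi-axes
m1 >= m2 >= m3 come from its eigenvalues.  Directions with zero crossings
are dropped with a warning (fewer than 9 usable directions aborts the fit:
6 unknowns).  The indices are the Benn pair I = m3/m1 and EA = 1 - m2/m1,
stated explicitly because different fabric traditions define them
differently.

## Blob analysis

Per labelled component: voxel count, physical volume, equivalent-sphere
diameter d_eq = (6V/pi)^(1/3), maximum-inscribed-sphere diameter and
sphericity d_ins/d_eq.  The inscribed radius is computed from the chamfer
transform restricted to the blob (neighbouring blobs count as background, so
watershed-separated touching grains are measured individually), as the
deepest distance minus half a voxel — i.e. from the deepest voxel centre to
the boundary surface.  Under this convention a digitised cube of edge a has
sphericity a / (a (6/pi)^(1/3)) = 0.806 as it should; a single-voxel blob is
treated as a degenerate sphere (d_ins = d_eq, sphericity 1).  Digitised
balls approach sphericity 1 from below as the radius grows; at radius 10 the
value is about 0.95, limited by the chamfer metric error and the half-voxel
boundary convention.  Blobs touching the VOI border are flagged
(`touches_border`) but never silently dropped; size filtering is an explicit
`min_voxels` argument defaulting to 1 (no filter).

## Skeleton analysis

`lkc_skeletonize` is sequential directional thinning: six sub-cycles per
pass in the fixed order U, D, N, S, E, W remove border voxels of that
direction that are simple points — removal preserves both the 26-object and
6-background topology, tested by the Malandain-Bertrand local
characterisation — and are not curve endpoints.  Candidates are collected
per sub-cycle and deleted sequentially with the simplicity test re-checked
at deletion time, which guarantees topology exactly.  Endpoint protection is
sticky: once a voxel has at most one object neighbour it is anchored
permanently.  Without this, zig-zag curve ends expose corner voxels with two
neighbours and erode step by step — the reference sequential thinning
implementations exhibit exactly this collapse on even-diameter cylinders.
The thinning family leaves the sub-cycle and scan order open and different
choices yield different, equally valid skeletons; determinism is the
requirement, not uniqueness.

The skeleton graph classifies voxels by 26-neighbour count (1 end,
2 interior, >= 3 node) and walks interior chains into branches typed
node-to-node, node-to-end or end-to-end.  Branch length sums voxel steps
weighted 1, sqrt(2), sqrt(3) times the voxel size.  Degenerate conventions,
fixed and tested: a pure cycle is one self-closing node-to-node branch
carrying one phantom graph vertex (so the first Betti number
beta1 = E - V + C is exact: a cycle gives 1 - 1 + 1 = 1); an isolated voxel
is an end-to-end branch of length 0 carrying no edge.  Junctions meeting
through straight orthogonal crossings form junction *clusters* under
26-adjacency (several adjacent voxels of degree >= 3); each cluster voxel is
a graph vertex and the zero-length branches between them cancel in beta1.

`prune_skeleton` removes node-to-end branches strictly shorter than the
threshold (in voxels, matching the unitless pruning parameters of thinning
protocols), re-extracting the graph until stable — pruning happens on the
skeleton volume and the graph is rebuilt afterwards, so a junction whose
spurs were removed correctly degrades to an interior voxel.  Cycles and
free-standing segments are never pruned.  Connectivity density is
beta1 per mm^3 of VOI.

## Trabecular morphometry

The morphometric indices use the indirect plate-model identities of
classical histomorphometry: TbTh = 2/BsBv (mm), TbN = BvTv/TbTh (mm^-1),
TbSp = 1/TbN - TbTh (mm), with BvTv the solid voxel fraction and BsBv the
configuration-count surface area over the solid volume.  The plate model was
chosen over direct sphere-fitting thickness because the two printed input
scalars of the worked example reproduce the three printed derived indices
to two decimals under exactly these identities, and because the identities
are exact for parallel-plate geometry — the package's slab phantom recovers
constructed thickness and separation within 10%, the residual coming from
the aligned-plate bias of the 13-direction surface quadrature.  Note the
standard semantics (TbTh in mm, TbN in mm^-1, TbSp in mm) are used; loose
unit labelling in parts of the literature swaps them, but only the standard
assignment makes the printed numbers mutually consistent.

## Phantoms: what they emulate and what they do not

The generator produces solids with analytic ground truth (attached as an
attribute): ball, hollow shell, torus, cylinder bundle (axes snapped to
voxel centres so the medial axis is a lattice line), slab stack (plates
offset away from the border so both faces of every plate are interior),
Poisson Boolean ball model with periodic wrap-around (stationary, coverage
1 - exp(-lambda v)), and an ellipsoid field with isotropic or aligned
orientations.  Digitisation is centre-in-solid with no antialiasing, making
voxel-count oracles exact to enumerate.  Gray-level phantoms assign a mean
per phase plus Gaussian noise, clipped and rounded to the dtype.

These phantoms emulate geometry, contrast and Poisson-type clutter.  They do
not emulate CT physics: beam hardening, ring artifacts, phase-contrast
fringes, partial-volume blur or spatially correlated noise.  Passing tests
therefore demonstrate correctness of the estimators on clean geometry and
well-separated gray modes, not robustness of any segmentation to
reconstruction artifacts — on real data the filtering and threshold
parameters remain the user's scientific responsibility.

## Protocols and problem sizes

The three pipelines (`run_pore_protocol`: median, Otsu, opening, then
basic/blob/skeleton analysis; `run_multiphase_protocol`: k-means, phase
mask, chamfer, H-minima, watershed, components, blob table;
`run_morphometry_protocol`: optional segmentation then the five indices) are
plain configurable functions: flat key-value config files, every stage
parameter echoed to the run log, stage-indexed intermediate volumes, and
reports free of timestamps so identical configs yield bit-identical files.
The erosion-dilation step of the pore protocol defaults to opening
(erosion first), with a `closing` flag to swap the order; opening is the
natural choice when the segmented phase is the pore space and isolated
misclassified voxels should vanish rather than be sealed.  Blob analysis in
the pore protocol runs on the opened mask (before any watershed
separation), where component counting reflects physical connectivity.

The test suite and the acceptance script run phantoms between 32^3 and
64^3 voxels with 64-128 MIL directions — sizes chosen so the full suite
completes in well under a minute on one core while keeping digitisation
errors inside the stated tolerance bands; the estimators themselves are
resolution-independent and the defaults (512 directions) target
production-size volumes.

## Known limitations

* Surface and curvature are local-configuration estimators: a few percent
  bias on smooth bodies, larger on strongly aligned plate fabrics.
* The thinning produces one member of the family of valid curve skeletons;
  medial *surfaces* (thin plates) collapse to curves by design.
* Anisotropic voxels, DICOM/HDF5 containers and multi-Otsu are out of scope;
  raw + sidecar and grayscale TIFF stacks are the supported formats.
* The watershed has no marker-imposition mode; over-segmentation control is
  via `h` only.
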