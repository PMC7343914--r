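---
title: "Virtual cleaning of encrusted skeletal remains: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual cleaning of encrusted skeletal remains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(speleoclean)
```

This vignette documents the models, numerical choices and limitations behind
`speleoclean`. The pipeline targets a concrete situation: a skeletal element
(here, a proximal femur) completely enclosed in a speleothemic calcite crust,
scanned with a clinical CT at anisotropic voxel size, where bone and calcite
HU distributions overlap enough that global thresholding and region growing
fail. Segmentation therefore has to be anchored by a human reader on sparse
slices, and everything downstream must be reproducible from those sparse
inputs.

## Geometry conventions

A `ct_volume` stores HU values as an `(nx, ny, nz)` array indexed
`[column x, row y, slice z]`, 1-based; voxel `(i, j, k)` sits at world
position `origin + ((i-1)dx, (j-1)dy, (k-1)dz)` mm. Only axial, identity-
orientation series are supported — oblique acquisitions are rejected rather
than resampled, because the whole protocol (contours, interpolation,
erasure) is defined slice-wise. When a DICOM series is read, slices are
ordered by their world z position, never by file name, and the z spacing is
*measured* from inter-slice positions rather than taken from the nominal
slice-thickness tag: nominal thickness, reconstruction increment and
effective z voxel routinely disagree in clinical practice, and the measured
spacing is the only self-consistent choice. Series with more than 1%
inter-slice spacing variation are rejected.

DICOM support is deliberately minimal (single-frame CT, Explicit VR Little
Endian, 16-bit signed pixels with linear rescale); the round trip is exact
for integer HU and is cross-checked in the test suite against an independent
DICOM implementation. A raw+JSON fallback format carries the same geometry
for workflows that should not depend on DICOM plumbing.

## Contours and shape-based interpolation

A contour is a closed simple polygon on one slice, in in-plane mm. The
normalised drawing convention — clockwise in image coordinates (y down),
starting from the "twelve o'clock" vertex, i.e. the vertex of minimal image
y relative to the centroid with ties to smaller x — mirrors how readers are
instructed to draw ROIs and makes contour files canonical and diffable. The
convention needs a geometric definition to be testable; the one above is
this package's.

Rasterisation uses the even-odd rule on pixel *centers* with strict
inequality at the boundary. Strictness is a reproducibility decision: no
result may depend on which viewer's boundary dialect produced a contour.
Multiple contours on one slice rasterise as their union; component-wise
matching across slices is not attempted.

Interpolation between keyframe slices is *shape-based*: each keyframe mask
is converted to a signed Euclidean distance field (negative inside), the
fields are blended linearly at the slice's fractional position, and the
interpolated mask is the sub-zero set. This choice is exact at the
endpoints, behaves predictably for convex-to-convex morphs (concentric
discs interpolate to the disc of interpolated radius), and is symmetric:
`interp(a, b, t) = interp(b, a, 1-t)`. When one side of a gap is empty, the
empty field is taken as a constant cap — the grid diagonal in pixels — so
the shape shrinks deterministically toward its own medial interior. Distance
fields are computed in pixel units, which assumes square in-plane pixels
(true of the targeted scans); the two in-plane spacings are carried
separately everywhere else.

The keyframe stride is the operator's main dial: on the smooth noiseless
phantom, Dice against ground truth is 0.94 at stride 20, 0.98 at stride 10
and exact at stride 1, and is monotone in the stride — all asserted in the
test suite. Slices outside the keyframe support stay empty: beyond-support
extrapolation would be invention.

## Virtual cleaning

Erasure writes `fill_hu` into the masked voxels. The default fill, −2048 HU,
lies below any achievable HU, which makes the "coincidence set" — masked
voxels that already held the fill value — empty, and the erased region
exactly recoverable by comparing template and original. The subtraction is
implemented as difference-support masking (original where the two differ,
uniform background elsewhere) rather than literal voxel arithmetic: literal
subtraction would produce HU *offsets*, not a volume containing the
specimen's own HU values, and the point of the template subtraction is a
dataset showing only the cleaned specimen. Consequently the cleaned volume
introduces no HU values that were absent from the original, apart from the
background constant.

## Isosurface extraction

Surfaces are extracted by marching tetrahedra on the Freudenthal (Kuhn)
six-tetrahedron cube decomposition. The decomposition is translation-
invariant and face-compatible between neighbouring cubes, and surface
vertices are created once per global grid edge, so the mesh is watertight
and crack-free by construction; triangles are wound so normals point away
from the supra-threshold side. On an analytic sphere sampled as a smooth
occupancy field (10 mm radius, 0.5 mm spacing), mesh area is within 0.2% and
enclosed volume within 0.2% of the closed forms, comfortably inside the 2%
and 1% bands the test suite enforces.

The HU threshold for the final rendering is a genuine free parameter of this
class of protocol, and no default can claim to reproduce any particular
operator's choice. When the caller gives none, the package uses the midpoint
between the background level and the 5th percentile of supra-background
voxels and logs the value; the command-line tool prints it rather than
hiding it.

## Osteometry

Von den Driesch's measures are defined for hands-on calipers; a mesh
pipeline must pick explicit geometric operationalisations, and results are
comparable only within-method (each report says which method produced it):

* **Shaft axis** — initial PCA of the vertex set (rejected if the principal
  extent is under 1.5× the second), head end detected as the extremity with
  the larger cross-sectional caliper, then iterative refinement as the
  principal line of *cross-section centroids* over the shaft region
  (default: the 40% of length farthest from the head). Section centroids of
  a tube lie on its axis regardless of the cutting angle, so this converges
  where surface PCA stays biased by the head and trochanter; on phantoms the
  recovered axis is within 0.2° of construction.
* **SD** — cross-sections at 0.5 mm stations along the shaft region; per
  station the maximal in-plane caliper (diameter of the section's convex
  hull); SD is the station minimum. Stations within 6% of the axial extent
  of the broken end are excluded: a plane near the transverse break cuts an
  oblique sliver of the end cap and would fake a small diameter.
* **DC** — algebraic least-squares sphere fit to the head band (default: the
  top 12% of axial length). A fit RMS above 10% of the fitted radius errors
  out as "not spherical" instead of returning a number; heavily truncated or
  badly interpolated heads fail loudly here by design.
* **Bp** — maximal caliper width of the proximal region (top 35% of axial
  length) projected perpendicular to the shaft axis, scanned over 1440
  in-plane directions via the projection's convex hull.

All three recover the phantom's closed-form truth within two voxels at zero
reader noise and are invariant under random rigid transforms to 0.5%
(measured: below 0.01%).

## Phantom and simulated readers

The generator emulates exactly the features that make the real problem hard,
and no more: a femur-like union of primitives (capped cylindrical shaft;
constant-radius oblique neck at 45°, a degenerate frustum chosen so the
proximal-breadth truth has a closed form; spherical head; lateral spherical
trochanter bump), a calcite shell whose thickness varies smoothly around a
mean, overlapping bone and calcite HU distributions (defaults
N(1300, 150²) vs N(1400, 150²), overlap coefficient ≈ 0.74), Gaussian blur
as a partial-volume surrogate, and additive HU noise. The default spacing
(0.33 × 0.33 × 0.67 mm) matches the anisotropy of the motivating scan class;
the shaft and head radii give SD 29.6 mm and DC 30.7 mm, the scale of an
adult wild-boar femur. Ground truth is the pre-degradation rasterisation:
blur and noise never touch the truth mask, and the three true measures
follow analytically from the spec (`SD = 2r_shaft`, `DC = 2r_head`,
`Bp = r_shaft + r_troch + l_neck/√2 + r_head`).

Test and acceptance runs use the same geometry at coarser spacing
(0.66 × 0.66 × 1.0 mm, ≈ 1.2 M voxels; ten small erase/subtract phantoms at
1.2 × 1.2 × 1.6 mm), which scales cost without changing any contract under
test.

Simulated readers trace the *exact* pixel-region boundary of the truth mask
on every k-th bone slice (one polygon per connected component, vertices on
the pixel-corner lattice so mask pixel centers are strictly inside), then
resample to `n_vertices` and jitter each vertex radially by N(0, σ²) mm.
When the requested vertex count is at least the traced boundary length,
resampling only inserts collinear points and the noiseless contour
rasterises back to the truth mask *exactly* — the property that anchors the
whole pipeline's noiseless identity tests. Radial jitter can fold a locally
concave boundary; the simulator redraws such a contour from its seeded
stream, keeping determinism. What the phantom does **not** model: trabecular
texture, beam hardening, scanner kernels, or anatomically faithful
trochanter shape. Passing tests demonstrate the pipeline's correctness and
stability, not clinical segmentation accuracy on real material.

## Cloud congruence metrics

Models from independent readers are compared as point clouds: area-weighted
uniform sampling (square-root barycentric trick) of a fixed number of points
per model — 10⁶ at study scale, 10⁵ in the test suite — then, for each point
of one cloud, the Euclidean distance to its nearest neighbour in the next
(exact kd-tree search; verified against brute force). Distances are
unsigned and the comparison is cyclic and directed (R1→R2, R2→R3, R3→R1).
"Within 1 mm" is strict (`d < 1.0`). Each mesh's sampling seed is derived
from the shared seed *and the mesh content*, so identical models receive
identical clouds and report exactly zero deviation — without this, two
perfect readers would appear to disagree by the sampling gap. Per-vertex
nearest-neighbour distances to a reference cloud export through PLY as a
`quality` channel for heat-map rendering. Rigid registration is out of
scope: models from one scan share a frame by construction.

## Radiocarbon calibration

Calibration evaluates, on a 1-year calendar grid (the resolution at which
such dates are printed), the posterior of the calendar age under a uniform
prior and a normal measurement model with variance σ² + σ_curve(t)²,
including the 1/√(σ² + σ_curve²) density normalisation — the convention of
standard calibration software, which matters when the curve error varies
along the grid. HPD regions are found by descending-density inclusion: the
smallest set of years whose mass reaches the level (0.6827 / 0.9545 for
1σ/2σ). On a discrete yearly grid the selected mass overshoots the level by
at most one year's mass; ranges are maximal contiguous runs. Each range is
reported with its absolute mass *and* its share of the level's total — the
share is what calibration software prints (shares sum to 1 within
rounding), and both are exposed so either convention can be checked.
Calendar years at or before 1950 BP are labelled cal BC as positive numbers
(cal BC = cal BP − 1950); the era flag is always explicit. Range endpoints
round to the nearest year; no 5-year rounding is applied.

The package bundles no calibration curve: published curves carry their own
distribution terms, and tests use synthetic curves (the identity curve makes
the posterior analytically Gaussian, and the suite requires agreement to
1 × 10⁻⁶ in density). The worked example against the published IntCal13
curve runs when the user drops `intcal13.14c` into `inst/extdata/`.

## Known limitations

* Holes in a slice's cross-section are not representable by the union-fill
  contour model (outer boundary and hole would union to the outer fill);
  long-bone cross-sections in this protocol have none.
* Shape-based interpolation blends composite slice masks; it does not match
  components across slices, so topology changes mid-gap morph through the
  blended field rather than splitting explicitly.
* The DICOM layer reads only what the package writes plus well-behaved
  Explicit-VR-LE single-frame CT; it is not a general DICOM library.
* Osteometric definitions are this package's operationalisations; absolute
  agreement with hands-on calipers on real bone is not claimed, only
  internal consistency, phantom recovery and rigid invariance.
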