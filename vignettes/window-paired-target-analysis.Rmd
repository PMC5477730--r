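---
title: "Comparing window-paired target volumes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing window-paired target volumes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctvdelta)
```

`ctvdelta` quantifies what changes when a head-and-neck target volume is
delineated against air on a lung CT window (L) instead of the standard
soft-tissue window (S): the geometry of the paired structures (volumes,
surfaces, Hausdorff distances), the clinical target volumes derived from
them by margin expansion and barrier cropping, and the dose coverage of
the lung-window target — in particular of the difference volume
`CTV_Δ = CTV_L − CTV_S` — under a plan optimized on the soft-tissue
target. This vignette records the methods, the tunable parameters and the
design decisions, so that the choices are auditable.

## Geometry on triangular meshes

Structures are carried as closed triangular meshes in the patient
coordinate system (mm, right-handed, axial slices orthogonal to z).
Volume is the signed-tetrahedron (divergence theorem) sum, exact for
polyhedra; surface area is the triangle-area sum. Before either is
reported, face windings are made consistent by propagating an orientation
across shared edges and the global sign is fixed so the enclosed volume is
non-negative — exported meshes frequently arrive with unreliable winding.
A mesh with open edges has no defined volume and is rejected with the
open-edge count.

The 3D Hausdorff distance is estimated by sampling each surface on a
deterministic barycentric lattice (default density 4 points/mm², plus all
vertices) and resolving every sample to the *exact* distance to the full
opposite surface — point-to-triangle, not vertex-to-vertex, which would
overestimate distances on coarse meshes. The point-triangle queries run in
compiled code behind a uniform spatial grid over triangle bounding boxes;
on meshes small enough to scan exhaustively, the accelerated result agrees
with an all-pairs brute force to 10⁻⁹ (this equivalence is a standing
test). The estimate is monotonically non-decreasing in sampling density;
density is exposed as a parameter.

The 2D variant slices both meshes into axial contours on a common slice
stack (default 2 mm spacing), densifies the contour polylines (0.5 mm
steps) and computes the symmetric point-to-segment Hausdorff distance per
slice. Two reductions were defensible for the per-structure summary —
the maximum or a median over slices; the package reports the **maximum
over shared slices** (the conservative choice) and always emits the full
per-slice map so any other reduction can be recomputed. Slices where only
one structure has contours are excluded from the summary and counted as
`unmatched_slices`, since a two-sided slice distance is undefined there.
Note that for strongly curved structures the per-slice distance can far
exceed the 3D distance near the structure's poles (for concentric spheres
of radii 10 and 15 mm the per-slice value is
`sqrt(225 − z²) − sqrt(100 − z²)`: 5 mm at the equator, growing without
bound toward the small sphere's pole); the per-slice map makes this
visible rather than hiding it in a single number.

Because the clinical literature's "median (±x)" notation is ambiguous
about its dispersion measure, cohort summaries report the median, the
sample standard deviation *and* the min–max range for every metric.

## Voxel-domain structure construction

Masks use the voxel-centre convention: a voxel belongs to a structure iff
its centre lies in the continuous set. The default grid is
1 × 1 × 2 mm — planning-CT-like anisotropy, chosen deliberately so the
anisotropic distance transform is exercised rather than idealized cubic
voxels.

**Margin expansion.** The GTV→CTV margin (default 8 mm, the clinical
standard for microscopic spread) is applied with an exact
Euclidean-distance-transform expansion: a voxel is occupied iff its centre
lies within the margin of an occupied input centre. Iterated structuring
element dilation was rejected: binary ball kernels accumulate shape error
for large margins on anisotropic grids. The transform is the separable
lower-envelope algorithm with per-axis spacing, exact to floating point;
it is tested against an exhaustive min-distance oracle. One property of
the centre convention is worth stating plainly: when a smooth body is
first digitized and then expanded, the digitized support reaches on
average about a quarter voxel short of the continuous surface in lattice
directions with no centre near the boundary, so the expanded volume of a
digitized 10 mm ball grown by 8 mm sits about 4% below the continuous
Minkowski volume at 1 mm resolution. This is inherent to every
centre-convention implementation (the same number falls out of the
standard distance-transform routines in other toolkits), shrinks with
voxel size, and cancels in *paired* comparisons such as S vs L, which is
what the package is for.

**Barrier cropping.** CTVs are cropped at anatomical barriers —
`result = mask AND NOT (air OR bone OR anatomical)` — with the
composition order fixed as *expand first, crop second*; the reverse would
let the margin re-enter a barrier. The barrier set keeps a third, generic
anatomical member (body outline, fascia) alongside air and bone so that
either a two-barrier or three-barrier reading of clinical practice is
expressible. The air barrier is defined through the lung-window preset
([−1000, 0] HU) restricted to the body.

**Mask ↔ mesh.** `mask_to_mesh` emits the exact voxel-boundary
isosurface: each face between an occupied and an unoccupied voxel becomes
an outward-oriented quad on the voxel-corner lattice. The mesh is closed
and consistently wound by construction, and its signed-tetrahedron volume
equals the voxel-count volume *exactly* — a stronger guarantee than a
smoothing isosurface would give, at the cost of a blocky surface whose
Hausdorff distances carry up to half a voxel of staircase. All
voxel-scale tolerances in the tests budget for this. `rasterize` goes the
other way by even-odd in-polygon tests of voxel centres against mesh
cross-sections, marking strictly interior centres.

## Dosimetry

DVHs are cumulative histograms of voxel-centre doses at a 0.01 Gy bin
width — fine enough that Dx% values interpolated linearly between bin
edges are stable well below the 0.1 percentage-point reporting precision
at a 70 Gy prescription. Dx% is "the largest dose received by at least x%
of the volume". The hot spot outside a target is the minimum dose among
the hottest complement voxels accumulated whole (no partial-voxel
interpolation) until 0.03 cm³ — whole-voxel accumulation matches common
treatment-planning behaviour and makes the value bit-stable.

Prescription normalization scales the entire grid by one factor so the
target D95% equals the prescription (70 Gy default). The factor uses the
exact voxel-dose order statistic rather than the binned curve, which
makes normalization idempotent and exactly commuting with uniform
scaling; metric extraction then uses the binned DVH.

## Plan acceptance rules

Objectives are three-level — per protocol / variation acceptable /
deviation unacceptable — over D95%, D5%, D98% and the external hot spot,
in percent of prescription: D95 per-protocol exactly 100% (±2% acceptable),
D5 and hot spot ≤107% (≤110% acceptable), D98 ≥95% (≥90% acceptable).
Decisions embedded in the engine:

* **Acceptance = absence of unacceptable deviation.** A
  variation-acceptable metric still passes. On the packaged 14-case
  coverage table this reading yields 13 accepted CTV_L rows — the only
  reading consistent with every printed per-case value.
* **Boundary values classify into the better level** (the printed
  inequalities are non-strict), e.g. D98 = 90.0% is variation-acceptable.
* **D95's "exactly 100%"** is evaluated with a 0.05-point tolerance so
  that one-decimal rounded inputs (99.95–100.05) are not spuriously
  demoted.
* **Under-coverage of CTV_Δ** is flagged when D98% falls *strictly* below
  the 95% per-protocol level. Applied to the packaged table this strict
  threshold reproduces all eight flagged difference volumes (94.1%
  flagged, 95.6% not) and no others; it is the only simple D98 rule that
  does.
* The packaged table prints D2 rather than D5; since no D2 objective
  exists in the protocol, D2 is treated as the volume-percentile metric it
  is and recorded as not-evaluated instead of being forced under the
  near-maximum bound. Metrics absent from the input are likewise skipped
  and recorded.

## The synthetic phantom

No patient imaging is distributable, so validation rests on a seeded
phantom that emulates the study's geometric structure: a C-shaped
annular-sector target (soft tissue, 0–80 HU) wrapping a cylindrical air
cavity (−1000 to −905 HU) inside a cylindrical body, with a bone cylinder
clipping the outer CTV edge and the body outline as the anatomical
barrier. The lung-window variant extends the sector radially *toward the
cavity* — the "tip of the iceberg" that soft-tissue windows miss — by a
depth solved from the requested volume-increase fraction
(`(V_L − V_S)/V_S`, default 0.09, the typical relative volume gain of
lung-window delineation); the extension must stop at the cavity surface.
Default geometry: cavity radius 8 mm, S-target 12–26 mm × 220° × 30 mm
on a 105 × 105 × 41 grid. These values give iceberg depths near 2 mm,
GTVs of ~30 cm³ and CTVs of ~100 cm³ — the clinical order of magnitude —
while the grid is aligned so the target's z-extent falls on whole slices
(no half-slice volume bias) and leaves headroom for the 8 mm margin plus
the full penumbra.

The dose stand-in is an analytic conformal field, not an optimizer (plan
optimization is out of scope): dose is a function of the signed
voxel-centre distance to the target surface — flat with a gentle +5%
central heterogeneity inside, Gaussian fall-off `exp(−s²/2σ²)` outside
(σ = 3 mm default, a clinically plausible penumbra scale), then D95%
normalization. Consequences, all verified by tests rather than asserted:
each plan meets every per-protocol objective on its own target; the dose
five penumbra scales away from the target is below 5% of prescription;
and the difference volume of the default phantom, lying 1–2 voxels into
the penumbra of the S plan, receives a D98% near 78% — far below the 95%
coverage level — while whole-CTV_L coverage barely moves because CTV_Δ is
under 2% of CTV_L. That is the study's qualitative finding reproduced by
construction.

Cohorts draw the volume fraction U(0.05, 0.13), outer radius U(24, 27) mm,
angular extent U(200°, 240°) and height from {26, 30, 34} mm (values whose
half-heights fall between slice centres, keeping the analytic ground
truth exact) around the defaults, one derived sub-seed per case, so a
14-case cohort brackets the emulated study's spread of target sizes and
effect magnitudes and is exactly reproducible from one seed.

What the phantom does *not* emulate — and what passing tests therefore do
not show about real data: free-form interobserver contour variation (the
S→L difference is a purely radial extension), CT noise structure and
artifacts, optimizer-shaped dose with OAR trade-offs, and non-convex
air/bone anatomy. One visible consequence: because the S/L difference is
confined to the air interface and the OARs sit far from it, OAR dose
differences between the paired plans are essentially zero in the phantom,
where clinical plans show small but nonzero spreads; the comparison
machinery is exercised, but its magnitudes are not clinically meaningful
here.

## Numerical choices and degenerate inputs

* Hausdorff sampling is deterministic (barycentric lattice), so repeated
  runs and the brute-force oracle see identical point sets; no
  Monte-Carlo noise enters any geometric quantity.
* Slicing nudges a plane by 1 µm when it passes exactly through mesh
  vertices; the package's own slice stacks fall between voxel-corner
  lattices, so this affects only hand-built meshes.
* Expansion by 0 is the identity; negative margins are rejected
  (contraction is a different operation with different barrier
  semantics). Expansion is clipped at the grid bounds — grids must be
  sized with headroom, as the phantom's are.
* Degenerate (zero-area) triangles contribute nothing to area and fall
  back to edge distances in point-triangle queries.
* Empty masks, empty meshes, grid mismatches, unknown metrics and
  malformed fixtures raise errors naming the violated contract rather
  than returning silent defaults.
* Problem sizes in the shipped tests — icospheres at subdivision ≤4
  (5 120 faces), phantom grids of ~450 k voxels, cohorts of 14 — were
  chosen so the full suite and the reproduction script each run in
  minutes on a single core while still exercising every code path at
  clinically representative scales.

## Known limitations

* Voxel-boundary isosurfaces make mask-derived Hausdorff distances
  staircase-quantized; sub-voxel surface placement (marching-cubes-style
  interpolation) would reduce this at the cost of the exact-volume
  guarantee.
* Centre-convention expansion under-reaches a digitized smooth surface by
  ~¼ voxel on average (quantified above).
* The DICOM pathway (RTSTRUCT/RTDOSE) is not implemented; STL/PLY/NRRD
  cover the supported workflows.
* The 2D Hausdorff summary is a maximum; cohort medians of per-slice
  values can be recomputed from the emitted maps but are not a built-in
  summary level.
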