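---
title: "Quality assurance for medical 3D printing: models and methods"
author: "printqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assurance for medical 3D printing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(printqa)
```

## The QA problem

A patient-specific anatomic model passes through three stages before it
reaches a surgeon's hands: volumetric imaging (usually CT), segmentation and
mesh processing, and the print itself. Each stage can distort geometry — a
thick slice staircases an oblique cortex, a smooth reconstruction kernel
erases thin trabecular detail, aggressive mesh "wrapping" swallows distal
vessels, and the printer adds its own deposition errors. A credible QA
program therefore needs (a) phantoms of exactly known geometry that can be
pushed through the *entire* chain, and (b) a quantitative way to compare a
printed model against the virtual model it came from.

`printqa` implements both halves in software: parametric generators for two
QA phantoms, a simulator of the CT acquisition effects that matter at QA
scale, the segmentation/extraction/registration/distance pipeline used to
validate printed models, and a seeded synthetic "printer" that injects known
errors so the whole loop can be tested against ground truth without
hardware.

## Phantom generators

`build_gen2_phantom()` constructs the multi-object accuracy phantom: a
50 × 100 × 5 mm positive base carrying line-pair ladders (0.5, 1.0 and
2.0 lp/mm per axis), a one-period sinusoidal curvature surface
(12.5 × 50 mm footprint, 7.5 mm peak-to-valley within a 10 mm envelope), a
20/10/20 mm cone, a cochlea-like spiral (tube annulus 1.8/2.5 mm, start–end
separation 10 mm) and a vertical vascular tree (10 mm segments of 5, 2.5,
1.25, 0.75 and 0.5 mm diameter with 2.5 mm/45° and 0.75 mm/25° side
branches); and a 50 × 100 × 12.5 mm negative base with recessed semi-spheres
(2.5, 5.0, 7.5 mm), a hexagonal recess (10 mm across flats) and a conical
recess (16.5 mm top, 10 mm bottom, 7.5 mm deep), with five ruler notches at
10 mm spacing along each edge. Three insert plates carry positives of the
recessed shapes for the qualitative fit test.

Design choices where the published description is silent:

* **Insert cone.** The listed negative cone (16.5/10/7.5 mm) is not the
  complement of the listed positive cone (20/10/20 mm). Since the insert
  objects are described as positives *of the shapes on the negative base*,
  the insert cone is built as the exact complement of the conical recess,
  and the 20/10/20 mm cone stands on the positive base as its own shape
  test.
* **Recess depths.** The hexagonal cylinder is 20 mm tall but the negative
  base only 12.5 mm; its recess is capped at 10 mm depth (2.5 mm floor).
* **Layout.** Object placement on the bases is spec-driven
  (`gen2_phantom_spec()$layout`) with a two-column grid and at least 5 mm of
  separation; overlapping or out-of-base placements raise a layout error.
* **Ruler markers.** Modeled as 1 × 1 × 0.5 mm recessed notches.
* **Curvature surface.** One full sine period along the 50 mm length; the
  7.5 mm figure is taken as peak-to-valley and the 10 mm figure as the total
  envelope height.

`build_gen1_phantom()` constructs the line-pair resolution block: 11 groups
of 5 air openings, each opening as wide as its neighboring bars. Published
sources do not list the physical bar widths, so the default ladder is
geometric from 3.0 mm down to 0.3 mm (ratio 10^-0.1 per group), bars 10 mm
tall and 5 mm deep on a 5 mm slab — small enough to print quickly, wide
enough that every opening stays well above the voxelization guard of
0.1 mm. Widths below 0.2 mm are refused.

All curved surfaces are tessellated with a chord error of at most 0.01 mm,
an order of magnitude below the 0.1–0.5 mm errors the pipeline is meant to
measure, and rings are sampled so that nominal diameters are hit exactly:
`measure()` on any component reproduces its defining dimension to better
than 10^-3^ mm.

### Constructive parts

A `tri_mesh` may consist of several closed parts, each signed `+1` (solid)
or `-1` (cavity). Inside/outside queries and the voxelizer resolve the
union of positive parts minus the union of negative parts, so the negative
base stays exactly parametric — its recesses are closed cavity solids whose
caps are coplanar with the slab top — and overlapping unions (for example a
branch cylinder rooted inside the trunk) voxelize correctly. The
divergence-theorem volume of a multi-part mesh is the signed sum over
parts; for parts that overlap (only the vascular branches do) it
over-counts the small shared lens, which is irrelevant to every dimension
the QA pipeline measures.

## The scan simulator

`simulate_scan()` composes three effects:

1. **Partial volume** (`voxelize()`): each voxel receives
   `background + (object − background) · f`, with the occupied fraction `f`
   integrated exactly along the slice direction and supersampled 3 × 3
   in-plane. Polymer in air is modeled as 120 HU against −1000 HU.
2. **Reconstruction kernel** (`apply_kernel()`): an in-plane Gaussian PSF —
   0.15 mm sigma for the sharp kernel, 0.60 mm for the smooth one, chosen so
   the line-pair phantom reproduces the familiar sharp-vs-smooth resolution
   ordering — and a through-plane boxcar of the slice thickness, the
   mechanism that staircases oblique surfaces at thick slices. Kernels are
   normalized, so the mean HU of a padded volume is conserved.
3. **Noise** (`add_noise()`): additive white Gaussian noise in HU,
   reproducible under the protocol seed, and disabled at sigma 0 (the
   high-dose regime used when scanning printed models for validation).

The simulator is deliberately *not* a projection/reconstruction model: beam
hardening, metal artifacts, correlated noise and dose are out of scope.
What passing tests show is that the pipeline recovers geometry under
partial volume, blur, slice averaging and white noise; real scanners add
artifacts this generator does not emulate.

## Segmentation and surface extraction

A printed model scanned in air is segmented by a single global threshold
(`threshold_segment()`, with an optional largest-component filter standing
in for region growing). `extract_surface()` runs marching tetrahedra on the
conforming six-tetrahedra cube decomposition; on a grayscale volume the
iso-level is placed at the object/background HU midpoint, which localizes
the surface with sub-voxel accuracy (a voxelized sphere's volume is
recovered within 1%). Values exactly at the iso-level are nudged to the
outside so that isolated half-occupied voxels do not spawn spurious shells.

`wrap()` operationalizes mesh "wrapping" as morphological closing with a
spherical element (exact Euclidean distance transform, radii in mm so
anisotropic grids behave) followed by filling of enclosed cavities. Closing
is extensive, increasing and idempotent — verified in the tests against a
brute-force dilate–erode oracle — and its destructive side effect is
exactly the clinical caution: at 1 mm radius the sub-0.75 mm vascular
branches lose their separation from the trunk while the trunk itself
survives. No "recommended" wrap radius is asserted; the package only
exposes the radius and measures its effect.

`smooth_mesh()` is Taubin lambda/mu smoothing (0.33/−0.34, scaled by
`strength`): it removes high-frequency surface noise while keeping enclosed
volume within 1% over 20 iterations, avoiding the silent shrinkage of naive
Laplacian smoothing. `overlay_contours()` produces marching-squares
contours of a mask slice (corner values averaged from adjacent voxels, so
the binary mask is anti-aliased) for axial/coronal/sagittal overlay review.

## Registration and signed distance

`register_icp()` aligns the scanned-model surface to the reference with
point-to-surface ICP: correspondences are exact closest points on the fixed
mesh (grid-accelerated, verified against a brute-force all-triangle scan to
10^-9^ mm), the update is the Kabsch SVD solve, and the RMS correspondence
distance is non-increasing by construction. Initialization tries the four
proper principal-axis alignments *plus* the centroid-only identity — the
latter matters because scanned models usually arrive in the reference frame
already, and the principal axes of nearly symmetric shapes are numerically
meaningless. Iteration stops when the RMS improves by less than 10^-4^ mm
or after 100 iterations. Correspondence trimming is available
(`icp_settings(trim =)`) but off by default, since validation scans are
near-complete overlaps.

`signed_distance()` evaluates, at every vertex of the probe (scanned)
surface, the exact distance to the reference surface, signed positive
outside the reference solid — excess material — and negative inside —
missing material. The sign convention is stated in every report because
published distance statistics rarely define it. `distance_stats()`
summarizes with min/max/mean and the population (n-divisor) standard
deviation, plus a 0.05 mm-bin histogram; `validate_model()` chains the whole
pipeline and can emit a color-coded PLY and a versioned JSON report. The
probe direction is scan-against-reference; a symmetric evaluation can be
obtained by calling `signed_distance()` both ways.

## Line-pair analysis and QA logging

`measure_gaps()` is a computational caliper: a probe ray crosses the bars
at mid-height, and each opening's width is the distance between the
opposing wall crossings — exact ray-surface intersections on a mesh,
interpolated 0.5-occupancy crossings on a volume (the half-maximum
convention of caliper jaws on a step edge). Openings with no crossing are
flagged fused with width 0. Per-opening readings are retained and averaged
per group.

`resolvable_frequency()` samples the profile at bar and opening centers and
computes each group's modulation relative to the coarsest group; a group is
resolved at relative modulation ≥ 0.2, a conventional detectability cutoff
(configurable, since human scoring of such patterns is visual). The finest
resolved group is the end of the contiguous resolved run, which makes the
index monotone under increasing blur.

`qa_record()` / `check_limits()` / `qa_log_append()` implement the
longitudinal half of phantom QA: measurements are checked against
per-feature operational limits (default ±0.5 mm until a site accumulates
its own benchmark — limit-setting is prescribed, the number is a starting
point) and appended to a diff-friendly CSV log with ISO-8601 timestamps.
Appending to a log with a different schema is refused.

## The synthetic printer

`simulate_print()` composes four seeded, ground-truth-recorded error
models: loss of thin features (morphological opening at half the minimum
printable diameter), uniform surface offset (the signed-distance field is
sampled on a 0.05 mm grid — exact point-to-surface distances in a narrow
band around the target level, coarse EDT elsewhere — and the offset level
set re-extracted), a smooth sinusoidal warp (three axis-aligned sinusoids
with seeded phases, rescaled so the peak displacement equals the stated
amplitude; amplitudes at or above a tenth of the wavelength are refused as
self-intersection risks), and a rigid misplacement drawn within stated
bounds. The 0.05 mm morphology grid sits an order below the target error
scale; the closed-loop tests use 0.1 mm where the object is several
centimetres across, which keeps memory modest while the band-exact
distances still localize the surface to a few micrometres.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run on one CPU in a few
minutes, using problem sizes chosen to keep that budget while staying in
the regime the methods are meant for: reference objects 14–24 mm across
scanned at 0.2 mm in-plane / 0.4 mm slices (2–5 M voxels), offsets
recovered on 0.1 mm morphology grids, brute-force oracles on meshes of at
most 500 faces and grids of at most ~64³ voxels. Other fixed choices:
vertex-merge tolerance 10^-6^ mm on STL read (facets are stored
independently and must be merged before watertightness means anything);
26-connected foreground with 6-connected background (the standard
complementary pair); binary masks contoured at 0.5; fit tests evaluated
geometrically at the nominal seated pose (no drop simulation), with a 1 nm
floor on the clearance comparison so exactly complementary surfaces pass at
zero clearance.

## Known limitations

* The negative base's recess caps are coplanar with the slab top; distance
  queries against such internal interfaces report 0 at the interface
  itself, which is irrelevant to penetration depths but means the raw
  triangle set is not a minimal boundary representation.
* The scan simulator's kernels are isotropic Gaussians; real reconstruction
  kernels have negative lobes and the smooth/sharp naming maps only
  qualitatively onto vendor kernels.
* Signed volume of a multi-part mesh double-counts overlap lenses (only the
  vascular branch roots overlap in the shipped phantoms).
* NIfTI is the only volume interchange format; DICOM series ingestion is
  not provided.
* ICP is rigid; flexible models that deform after printing are outside the
  validation model's assumptions.
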