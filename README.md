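# printqa

Quality assurance tooling for CT-based anatomic modeling and medical 3D
printing, for the medical physicists, radiology technologists and
engineers who run a hospital 3D-printing lab.

A printed anatomic model is only as accurate as the weakest step of its
production chain: image acquisition, segmentation and mesh processing, and
the print itself. `printqa` puts that whole chain under test, in software:

* **QA phantoms.** Parametric generators for a line-pair resolution block
  (11 groups of 5 air openings of equal bar/gap width) and a two-plate
  accuracy phantom (semi-spheres, hexagonal cylinder, cones, curvature
  surface, ruler, cochlea-like spiral, branching vascular tree, and
  positive inserts that seat into their negative recesses). Every
  dimension is exact by construction, so the phantom is its own gold
  standard.
* **Scan simulation.** Partial-volume voxelization of a mesh plus
  reconstruction-kernel blur (sharp/smooth), slice-thickness averaging and
  seeded Gaussian noise — the acquisition effects that decide what survives
  segmentation.
* **Segmentation and processing.** Threshold segmentation, sub-voxel
  marching-tetrahedra surface extraction, morphological wrapping (closing +
  hole fill) with its measurable thin-feature loss, volume-compensated
  Taubin smoothing, and slice-overlay contours for review.
* **Printed-model validation.** Rigid ICP registration of the scanned
  print to its reference and a point-by-point **signed surface distance**
  (positive = excess material, negative = missing), summarized as
  min / max / mean / SD with a 0.05 mm histogram, exportable as a
  color-coded PLY and a JSON report. For a physical model the paper-trail
  is: print, rescan at high resolution, threshold, extract, register,
  measure.
* **Line-pair QA and logging.** Computational caliper readings of the air
  gaps against nominal, resolvable-frequency analysis under different
  kernels, and an append-only CSV QA log checked against operational
  limits.
* **A synthetic printer.** Seeded error models — uniform offset, sinusoidal
  warp, rigid misplacement, loss of thin features — with recorded ground
  truth, so the entire validation loop is testable closed-loop without a
  printer.

Meshes are STL in and out (PLY for annotated surfaces), volumes are NIfTI,
and everything is millimetres and Hounsfield units.

## Worked example

```r
library(printqa)

# build the accuracy phantom and inspect one component
ph <- build_gen2_phantom()
ph$negative_base
#> tri_mesh 'gen2_negative_base'
#>   1242 vertices, 2420 faces, 16 part(s)
#>   bbox [0.000, 0.000, 0.000] to [50.000, 100.000, 12.500] mm
#>   area 15146.706 mm^2, volume 60429.952 mm^3, watertight: TRUE

m <- measure(mesh_part(ph$positive_base_assembly, "cone_positive"))
sprintf("cone: bottom diameter %.3f mm, height %.3f mm",
        m$bbox[2, 1] - m$bbox[1, 1], m$bbox[2, 3] - m$bbox[1, 3])
#> "cone: bottom diameter 20.000 mm, height 20.000 mm"

# qualitative print check: do the positive inserts seat in their recesses?
fit_test(ph$insert_spheres, ph$negative_base, clearance = 0.05)
#> fit test: FITS (max penetration 0.0000 mm, allowed 0.0500 mm)

# closed loop: "print" a reference model with 0.1 mm over-deposition,
# rescan it at 0.2 / 0.4 mm, and validate against the reference
ref <- prim_sphere(14)
printed <- simulate_print(ref, print_error_model(offset = 0.1, voxel = 0.1))
scan <- simulate_scan(printed$mesh,
                      scan_protocol(in_plane = 0.2, slice_thickness = 0.4))
validate_model(ref, scan)
#> distance_report: n = 48634
#>   mean 0.0959 mm (range 0.0264 to 0.1681), SD 0.0192 mm
#>   registration RMS 0.0975 mm
```

The report recovers the injected +0.1 mm offset: the mean signed distance
is +0.096 mm (positive = excess material), with the residual spread coming
from voxel discretization. `validate_model(..., annotated_ply =, json =)`
additionally writes the color-coded surface and a machine-readable report.

A thin command-line front end over the same functions is installed at
`inst/scripts/printqa` (`printqa make-phantom`, `printqa scan`,
`printqa segment`, `printqa validate`, `printqa linepair`,
`printqa fake-print`, `printqa mesh-info`).

## Documentation

The methods vignette (`vignettes/printqa-methods.Rmd`) describes the
models and assumptions: the phantom design decisions, the scan simulator's
scope, the sign and SD conventions of the distance report, the
morphological definitions behind wrapping and thin-feature loss, and known
limitations.
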