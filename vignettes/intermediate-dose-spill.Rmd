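---
title: "Predicting intermediate dose spill for Gamma Knife radiosurgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting intermediate dose spill for Gamma Knife radiosurgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gkr50)
```

## The problem

In cranial stereotactic radiosurgery (SRS) the dose outside the target falls
off steeply, but the *intermediate* dose — the cloud receiving around half
the prescription — still bathes normal brain and drives the risk of
radionecrosis, especially when several metastases are treated in one session
or a patient is re-treated.  The standard scalar for this spill is

$$R50\% = \frac{V_{IDC50\%}}{V_{PTV}},$$

the volume of the 50%-of-prescription isodose cloud divided by the planning
target volume (PTV; in Gamma Knife convention the target itself, with zero
margin).  A planner looking at an achieved R50% has no absolute scale: is
3.6 good for this target, or sloppy?  `gkr50` answers that with a geometric
lower-bound prediction of R50% computed from nothing but the target's volume
and surface area.

## The model

Idealise the target as a sphere of the same volume, with effective radius

$$r_{PTV} = \left(\frac{3 V_{PTV}}{4\pi}\right)^{1/3}.$$

If the 50% isodose surface sits a radial distance $\Delta r$ outside the
target surface, the spill of the ideal sphere is the concentric-shell ratio
$((r_{PTV}+\Delta r)/r_{PTV})^3$.  A real target with surface area
$SA_{PTV}$ carries proportionally more shell, giving

$$R50\%_{Analytic} = 1 + \frac{SA_{PTV}}{4\pi r_{PTV}^2}
  \left[\left(\frac{r_{PTV}+\Delta r}{r_{PTV}}\right)^3 - 1\right].$$

For a perfect sphere the prefactor is 1 and the expression collapses to the
shell ratio exactly (`r50_analytic()` reproduces this to machine precision;
it is one of the package's property tests).  Because $\Delta r$ is
calibrated from plans optimised for the *steepest achievable* dose falloff,
the prediction is a lower bound: a clinical plan should land at or above it,
and the excess is a meaningful plan-quality signal.

## The dose drop-off parameter

$\Delta r$ cannot be computed from first principles; it is a property of the
machine and beam energy.  For the Gamma Knife Icon (192 Co-60 sources,
4/8/16 mm sector collimators) it was calibrated from eleven spherical
phantom plans between 0.001 and 44.91 cm³, each planned for minimal spill,
by measuring $\Delta r = r_{IDC50\%} - r_{PTV}$ (both radii equivalent-sphere
radii, `measured_delta_r()`).  The package ships the published piecewise fit
(`default_gk_icon_model()`):

* $V \ge 1$ cm³: $\Delta r = -0.018 + 0.2424\,V^{1/3}$ — a cube-root law, as
  expected when falloff distance scales with target size;
* $V \le 1$ cm³: $\Delta r = 0.5278 + 0.5730\,V - 0.2871\,V^{2/3} -
  0.5845\,V^{1/3}$ — the rise at very small volumes is a machine
  characteristic: below the 4 mm collimator a single shot's 50% cloud stops
  shrinking with the target.

```{r}
m <- default_gk_icon_model()
eval_delta_r(m, c(0.001, 0.1, 1, 20.41, 44.91))
```

At the boundary both branches are evaluated and averaged (0.2268 cm here).
The printed coefficients agree there only to ~0.005 cm because they are
rounded to four decimals; the package treats that slack as part of the
published model's definition, while freshly fitted models must be continuous
to 1e-9 cm.

### Refitting for another machine

`fit_delta_r_model()` refits both branches to phantom measurements by
least squares with the branch exponents fixed (1/3, 2/3, 1) and the
continuity constraint $\Delta r_{low}(V_b) = \Delta r_{high}(V_b)$ imposed
*exactly*, by eliminating the high-branch constant and solving the reduced
ordinary least-squares problem by QR.  This is deterministic, needs no
iterative solver, and makes fit-then-generate an identity on noiseless data
from any continuous model in the family (tested to 1e-6).  Design choices
worth stating:

* **Fixed vs free exponent.**  The cube-root exponent is fixed by default —
  it is the published form, and freeing it makes the continuity constraint
  nonlinear for no benefit on Icon data.  For machines with a different
  beam-shaping device, `free_exponent = TRUE` profiles the high-branch
  exponent by one-dimensional optimisation over an inner linear solve.
* **Weighting.**  Unweighted; the calibration protocol gives no
  per-measurement uncertainties.
* **Extrapolation.**  Outside the calibrated 0.001–44.91 cm³ range the model
  warns but evaluates; a non-positive $\Delta r$ (the cube-root branch
  crosses zero near $4\times10^{-4}$ cm³) is a hard error rather than a
  silent floor.

Refitting the bundled phantom table reproduces the published curve with a
worst residual of about 0.023 cm, comfortably below the published fit's own
worst residual of 0.035 cm at 3.95 cm³.

## Surface area from DICOM-RT contours

Planning systems for the Gamma Knife do not report target surface area, so
the package computes it from the RT structure set.  `read_rtstruct()`
parses CLOSED_PLANAR contours (Explicit VR Little Endian; coordinates
converted mm to cm at the boundary, never inside computations) and
`contours_to_mesh()` closes them into a watertight triangle mesh:

* consecutive slices' rings are paired by maximal bounding-box overlap
  (centroid distance breaking ties) — sufficient to disambiguate disjoint
  lobes without a polygon-clipping dependency;
* paired rings are stitched by an advancing front that walks both rings in
  lockstep along normalized arc length after centroid registration, with
  exact ties resolved toward the smaller triangle.  Pure greedy
  minimal-area advancing is *not* used: on rings of unequal circumference it
  degenerates into two fans sharing a seam edge, which is non-manifold;
* terminal and unpaired rings are capped by ear-clipping (with a fan
  fallback for non-simple snapped rings);
* orientation is normalised so the signed divergence-theorem volume is
  positive; `mesh_volume()` returns its absolute value, so the result is
  orientation-independent.

Surface area is the sum of triangle areas (`mesh_surface_area()`), with
zero-area triangles dropped and counted.

### The small-structure pathology and its detector

The isoperimetric inequality says a sphere has the least surface area of any
solid of a given volume — so a *valid* closed mesh can never have less area
than the equal-volume sphere *of its own enclosed volume*.  Yet contour
meshes of very small structures are reported with non-physical areas (the
bundled clinical table's smallest target, 0.011 cm³, has a recorded area of
0.21 cm² against a sphere bound of 0.24 cm²).  The mechanism is pixelation:
contour vertices snap to the image grid, and the resulting mesh understates
*both* area and volume relative to the planning system's volume.  The
mismatch is therefore only visible when mesh area is compared against the
sphere bound of the *planning-system* volume, and that is how the detector
works: `mesh_surface_area(mesh, reference_volume = v_plan)` raises
`nonphysical_sa` when the area undercuts the bound of the reference volume.
With no reference volume the mesh's own volume is used, and the diagnostic
is provably silent for valid meshes — the package tests that as an
isoperimetric property.  Meshes whose smallest ring spans ≲3×3 pixels (or
fewer than 8 vertices) additionally carry a `resolution_warning`.

## Synthetic fixtures

`make_structure()` slices analytic solids (sphere, ellipsoid, two disjoint
lobes) into contour stacks at configurable slice spacing and ring sampling,
optionally snapping vertices to a pixel grid; every fixture carries the
analytic volume and area of the ideal shape, so mesh code is tested
closed-loop.  Pixelation is modelled by vertex snapping rather than full
rasterisation — enough to reproduce the small-structure pathology
(a 0.011 cm³ sphere contoured at 0.1 cm spacing and 0.1 cm pixel pitch
meshes to ≈0.16 cm², below the 0.24 cm² bound), and much simpler; what it
does not emulate is planning-system-specific contour smoothing or
partial-voxel volume accounting.  `make_phantom_calibration_set()` inverts
the drop-off relation to synthesise phantom measurement sets with optional
Gaussian noise; seeds are mandatory arguments and generators never touch the
global RNG stream.  Slice planes are placed at half-integer multiples of the
spacing, so a slice never passes exactly through a pole.

What passing these tests shows — and does not show — about real data: the
fixtures establish correctness of the geometry pipeline (convergence to
analytic areas and volumes as resolution refines, watertightness, unit
handling) but they are ideal axially-convex solids; clinical structures with
branching lobes that merge and split between slices exercise the ring
matcher beyond what the generator emulates, and for those the voxelise-and-
march approach of general mesh libraries may be preferable.

## Validation statistics

`compare_batch()` scores a table of clinical targets: for each target the
analytic prediction (from measured area, or the equal-volume-sphere
approximation under `sa_policy = "sphere_approx"`), the achieved
R50%, and their Difference (clinical − analytic); excluded targets — e.g.
those whose 50% clouds merge with a neighbour's so no per-target cloud
volume exists — are carried with machine-readable reasons, never dropped.
The Difference distribution is summarised by `box_stats()`: quartiles by
linear interpolation of order statistics (R's type 7, the spreadsheet
convention — recorded in every report, and the outlier partition on the
bundled data is robust to the standard alternative conventions), Tukey
fences at 1.5×IQR (configurable, since published box plots rarely state
their rule).

```{r}
report <- compare_batch(table2_plan_targets(), default_gk_icon_model())
report$stats
```

On the bundled 35-target table the median Difference is 0.92 with one
outlier below the lower fence and three above the upper — the low one being
the pixelation-afflicted 0.011 cm³ target, the high ones targets from an
11-target session, where dose "over-spray" from neighbouring shots inflates
each target's achieved spill.

Since a sphere minimises surface area, the sphere-approximation prediction
is ≤ the actual-area prediction for every physically consistent area; the
package asserts this bound across the clinical table and meshed fixtures.
It fails only where the recorded area itself is non-physical (the 0.011 cm³
target), which is exactly the diagnostic's purpose.

## Numerical policy

* All computation in cm / cm² / cm³; conversions only at I/O boundaries.
* Rounding to printed precision happens in reporting, never in computation.
* Table comparisons in the test-suite use ±0.05 on recomputed analytic
  values (±0.10 for the 0.011 cm³ target): areas printed at 2–3 significant
  figures propagate ~±0.01–0.03 into R50%.
* Problem sizes: sphere-convergence tests use three refinement levels from
  0.2 cm/16 vertices to 0.05 cm/64 vertices; the noisy-recovery simulation
  uses 22 measurements at σ = 0.01 cm.  These run in seconds and are already
  well inside the asymptotic regime the tests probe.

## Limitations

* Hole-containing (toroidal) ROIs and branching the bounding-box matcher
  cannot disambiguate are rejected, not mis-meshed.
* The drop-off calibration is specific to the Gamma Knife Icon; applying it
  to another Co-60 device requires refitting (the package provides the
  fitting tools, including the free-exponent variant).
* Overlapping 50%-isodose clouds are represented as exclusions; apportioning
  a merged cloud among targets is out of scope.
* DICOM support is deliberately minimal: Explicit VR Little Endian
  structure sets only; dose grids are accepted as arrays, not RTDOSE files.
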