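---
title: "Methods: simulated LiDAR surveys and alpha-shape shoot volume for defoliated vineyards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated LiDAR surveys and alpha-shape shoot volume}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Pruning weight (the dry biomass of the one-year canes removed in winter) is
a standard proxy for grapevine vigor, and mapping it along rows supports
variable-rate management and automated pruning. `vinescan` implements a
complete proximal-sensing workflow for estimating that biomass without
contact: a 2D time-of-flight laser scanner rides a slow platform along the
row, an RTK-GNSS receiver acts as the travel-axis encoder, the fused scans
become a 3D point cloud of the defoliated canopy, and the enclosed volume
of a 3D alpha shape over the filtered shoot cloud serves as the volume
surrogate that is regressed against biomass.

Because no field campaign data accompany this package, a parametric scene
generator stands in for the vineyard: every synthetic stand has an
analytically known shoot volume and biomass, which makes the whole chain
testable end to end.

## The synthetic vineyard

`scene_spec()` / `build_scene()` produce a cordon-trained, spur-pruned row
in its winter state.  Geometry and defaults, with the reasoning:

* **Layout** — 5 treatments x 3 plots x 10 vines (150 vines), one batch per
  plot, laid out consecutively along a single row with a 0.6 m gap, a post
  and a white-sphere marker at each batch boundary.  Vine spacing 1.0 m,
  inter-row distance does not matter (only one row is scanned).
* **Vines** — trunk to a 1.0 m cordon; each vine carries on average 18
  canes rising from spurs spread along 95% of the vine's cordon span.  A
  mature vine retains roughly 15-30 one-year shoots, and with the default
  cane dimensions 18 canes give ~0.3 kg of dry prunings per vine, a
  realistic figure.  The near-continuous spur line also reproduces how a
  spur-pruned row looks: cane bases form an almost unbroken line of wood
  along the cordon.
* **Canes** — chains of 2-4 tapered frusta, base radius ~4 mm truncated at
  5 mm (diameters stay below 1 cm), tip radius 40% of the base, length
  ~1.2 m.  Tilt from vertical has 8 deg s.d.; the tilt azimuth is held
  near the trellis plane (15 deg s.d.) because vertical shoot positioning
  presses canes between catch wires — they fan along the row, not across
  it.
* **Treatments** — a vigor multiplier (0.7..1.3 by default) scales cane
  count and length per treatment, so batch biomass spans a realistic range
  and regressions have something to recover.
* **Structures** — posts (r = 4 cm, 1.8 m), two horizontal wires
  (r = 1.5 mm at 1.4 and 1.8 m) and marker spheres.  Wires are modeled for
  realism of the returns but flagged negligible: they are never counted in
  the analytic truth, and they are not masked out of the cloud by default
  (see filtering).
* **Truth** — `batch_truth()` sums the closed-form frustum volumes
  `pi*h/3*(r0^2 + r0*r1 + r1^2)` of the shoot segments per batch;
  biomass = wood density x volume with a configured density of 450 kg/m3
  (a typical dry-wood figure; a configuration default, not a measured
  value).

What the generator does **not** emulate: leaves (the survey is of
defoliated vines by design), bark texture and non-circular cane sections,
multiple rows and inter-row occlusion, soil micro-relief beyond a plane,
and real GNSS multipath.  Tests passing on these scenes show the pipeline
is correct and well-behaved under the stated acquisition model; they do
not certify accuracy on field data.

## Acquisition model

`sensor_config()` mirrors a general-purpose outdoor scanner: 270 deg field
of view at 0.25/0.5 deg steps, 0.5-20 m window, 12 mm (1 s.d.) Gaussian
range noise, 1 mm range quantization, 25 or 50 Hz.  The sensor sits 1.20 m
above ground, facing sideways about 1 m from the row; the beam angle is
zero on the horizontal toward the row and positive upward, so the vertical
transect is symmetric.  The scan plane is perpendicular to travel.

`trajectory_spec()`/`simulate_trajectory()` move the platform in a
straight line below 3 km/h; at the operational 0.5 m/s and 50 Hz the
inter-slice spacing is 10 mm.  Optional sinusoidal roll/pitch/yaw and
lateral wobble emulate an uneven alley.  `simulate_scan()` ray-casts every
beam against the scene frusta, spheres and ground (exact quadratic
intersections), then applies noise, quantization and the measurement
window.  `generate_nmea()` emits checksummed GGA sentences at 10 or 20 Hz
with 2 cm per-axis noise, on a local tangent plane anchored at a declared
origin.  GGA times carry two decimals, which is why the supported fix
rates divide 100 Hz.

## Registration

`georeference()` drops invalid beams, converts each beam to the sensor
plane (`y = r cos theta`, `z = mount_height + r sin theta`), and applies
the pose interpolated at the frame timestamp: intrinsic Z-Y-X (yaw, pitch,
roll) rotation plus translation, then an optional configurable shear along
the travel axis (`x += s_y y + s_z z`, identity by default).  Fix
positions are first smoothed with a centered 0.5 s moving average — exact
for the nominal constant-velocity run, including the edges, where the
window shrinks symmetrically, while attenuating the centimeter white
noise of individual RTK fixes — then interpolated linearly at the frame
timestamp.  Yaw is the local travel direction estimated over a 1 s
baseline:
consecutive 10 Hz fixes are only 5 cm apart, so differencing adjacent
fixes would turn 2 cm RTK noise into tens of degrees of heading error and
smear the cloud laterally; over a 1 s window the error drops to a couple
of degrees, and for the nominal straight run the estimate is exact.  Roll
and pitch default to zero (the rig carries no inertial unit).  Frames
outside fix coverage are dropped and counted, never extrapolated.

## Filtering

The default chain per batch, each stage a strict subset operation:

1. `crop_batch()` — keep `x` in the batch's half-open interval (half-open
   so adjacent batches never double-count).
2. `cut_below_height()` — keep `z >= z0`, the bud-height cross-section that
   removes soil, stump and cordon returns.  Ties are kept.
3. `mask_training_structures()` — split out points inside capsules around
   the post axes and spheres around the markers.  The default mask margin
   of 8 cm beyond the structure radius covers the scatter of structure
   returns (range noise spreads points up to ~5 cm along the beam, with a
   little residual positioning error on top); the scene generator keeps
   cane wood at least 15 cm from post axes, as a real planter would, so
   the masks capture virtually all structure returns without swallowing
   shoot points.  Wires are deliberately not masked: their returns are
   negligible in volume, while a capsule wide enough to catch their noisy
   returns would cut a 10 cm slab out of every cane crossing the wire.
4. `sor_filter()` — statistical outlier removal: mean distance `d_i` to
   the k = 64 nearest neighbors, single pass, removing
   `d_i > mean(d) + 1 * sd(d)`.  This is the conventional rule of
   point-cloud toolboxes; a stricter literal variant (`d_i > sd(d)`) is
   available via `rule = "sigma_only"`.  k is clamped to n-1 on tiny
   clouds rather than failing.

The order (crop, cut, mask, SOR) is logged in the per-batch report; SOR
runs last so that its global statistics describe the batch being measured.

## The alpha-shape volume estimator

`delaunay3d()` builds the Delaunay tetrahedralization from first
principles (incremental Bowyer-Watson with ghost tetrahedra over the hull
and extended-precision predicates), so the finite tetrahedra are exactly
the Delaunay cells of the input.  Numerical choices:

* Input points are always jittered by a seeded uniform offset of 1e-9 of
  the bounding-box extent.  Gridded and quantized data (range quanta,
  regular sampling) are full of cospherical quadruples; the jitter makes
  those configurations measure-zero while perturbing any volume by orders
  of magnitude less than a range quantum.  The jitter and insertion order
  derive from a fixed seed, so results are reproducible.
* Near-coplanar tetrahedra (relative determinant below 1e-12) report an
  infinite circumradius and can never enter a finite-alpha complex; a
  fully coplanar input yields an empty complex with a warning.

`alpha_complex(points, alpha)` retains tetrahedra with circumsphere radius
at most alpha — **alpha is a length in meters**, matching the semantics of
the R alpha-shape tooling this workflow standardizes on (so alpha = 0.1
means 0.1 m; squared-radius conventions are not used).  The enclosed
volume is the sum of retained tetrahedron volumes, which is exact because
tetrahedra of a tetrahedralization have disjoint interiors.  Retained sets
are nested in alpha, so the volume is monotone and reaches the convex-hull
volume once alpha exceeds the largest circumradius.

**Connectivity.** The "free of voids" check behind alpha selection needs a
component count.  The alpha complex of computational geometry contains
lower-dimensional simplices as well, and two solid chunks joined by an
alpha-exposed edge form one connected shape with no void between them.
Counting components of the retained tetrahedra by shared faces alone would
instead leave every isolated 4-point sliver of a thin, noisy cane string
as its own "component" — on realistic scans of sub-centimeter canes a few
such slivers always exist, and the count would never reach one.
`alpha_complex()` therefore counts connected components over the covered
points, connecting them through retained tetrahedra and through Gabriel
edges (empty diametral sphere) no longer than 2 alpha.  The volume is
unaffected: only tetrahedra contribute volume.

`select_alpha()` implements the selection rule "smallest enclosed volume
while still a solid, void-free surface": volumes are monotone, so this is
the smallest candidate whose complex is a single component covering at
least 99% of the points.  The 99% default tolerates the handful of stray
points that survive outlier removal on any real scan.  If no candidate
qualifies the largest is returned with a warning.

`volume_without_structures()` is the subtraction step
`max(0, V_total - V_structures)` that removes the trellis contribution
from a batch total.

### Known behavior of the estimator

At the operational sampling density (0.5 deg steps, 10 mm slices, one-sided
scanning), alpha = 0.1 m produces a complex that bridges between
neighboring canes — the enclosed volume is an envelope of the occupied
canopy space, one to two orders of magnitude above the true wood volume.
That envelope still tracks vigor, which is exactly how it is used in the
regression layer.  True wood-volume recovery requires sampling the full
circumference of each cane densely: with 1 mm slices, 0.1 deg steps, both
row sides and well-separated canes, the estimator recovers the analytic
truth within a few percent (the parameter-recovery test runs that
configuration).  One-sided scanning can never do better than the visible
half of each cane, and cane tips thinner than ~2 mm are usually lost to
the beam grid and outlier removal — an underestimation intrinsic to the
geometry.

## Statistics

`linear_fit()` is plain OLS with the classical two-sided t test on the
slope; `fits_by_group()` fits per treatment plus pooled, skipping groups
with fewer than 3 records; `anova_records()` fits
`biomass ~ predictor + treatment` and reports the sequential (type-I)
table with the LiDAR predictor entered first, asking whether treatment
explains anything beyond the scanner reading.  No robust errors and no
multiplicity correction are applied — the output mirrors the plain
estimate/SE/p tables this kind of survey reports.

## Reproducibility and problem sizes

All randomness flows from explicit integer seeds; the pipeline splits one
master seed into per-stage sub-seeds and `run_pipeline()` writes a
manifest with the config, seeds, stage counts and output checksums, so a
run is reproducible bit for bit.

The test suite exercises the pipeline at deliberately compact sizes chosen
to probe each property rather than to reproduce a campaign: single batches
of 2-10 vines for selection and recovery, 15 three-vine batches for the
regression layer, brute-force oracles up to 2,000 points, and 500
simulated replicates for the ANOVA null.  The acceptance script runs the
full 10-vine batch at the operational settings.

## Limitations

* The registration trusts GNSS alone; roll/pitch disturbances are not
  corrected (no IMU), only simulated if asked.
* Scan matching between the two sides of a row is not implemented; the
  two-sided recovery fixture relies on both passes sharing one noise-free
  frame.
* The alpha-shape volume at field sampling density is an envelope
  surrogate, not a wood volume (see above); comparisons across batches
  assume a common acquisition geometry.
* The synthetic biomass link `biomass = density x volume (x weighing
  noise)` is exact by construction; field regressions face additional
  variance the generator does not model.
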