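---
title: "Anisotropic infill mechanics and conformal toolpath planning: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anisotropic infill mechanics and conformal toolpath planning: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anisoprint)
```

`anisoprint` plans direct-ink-write 3D prints whose infill lattice
produces a controlled directional stiffness, as used in soft-tissue
simulants for surgical training. This vignette documents the models,
their assumptions, the tunable parameters, and the design choices made
where the design space was genuinely open.

## The voxel homogenization model

The infill is built from alternating layers of parallel print lines,
each layer orthogonal to the previous one. The repeating unit — one
line segment from each of the two layer families plus the adjacent gaps
— is the *voxel*. Its microdimensions are the line widths `w1, w2`
(mm), line heights `h1, h2` (mm), and pitches `L1, L2` (mm); the
constituent cured-ink moduli are `E1, E2` (kPa). The in-layer spacings
are `s1 = L2 - w1` and `s2 = L1 - w2`.

Loading along the layer-1 line direction strains the layer-1 lines and
the layer-2 sublaminate equally (parallel, Voigt-like coupling), while
within the layer-2 sublaminate the line and spanning-gap segments carry
the load in series. Writing `VL1 = w1 h1 L1`, `VL2 = w2 h2 L2`,
`VS1 = L1 h1 (L2 - w1)`, `VS2 = L2 h2 (L1 - w2)` and
`VB = L1 L2 (h1 + h2)`, the apparent moduli are

$$E_L = \frac{V_{L1} E_1\,[V_{L1} E_1 + (V_{S2}+V_{L2}) E_2]}
             {V_B\,[V_{L1} E_1 + V_{S2} E_2]},$$

$E_T$ by exchanging the layer indices, and the anisotropic ratio is
$\gamma = E_L/E_T$. The volume definitions satisfy
`VL1 + VS1 + VL2 + VS2 = VB` exactly — the lines and gaps tile the
voxel box — and the package treats this conservation identity as a
structural invariant (property-tested on 1,000 random voxels). `VB`
carries the full `L1 L2` cross-section; without the `L1` factor the
identity fails, which is how the implementation pins the formula down.

Assumptions worth knowing:

* **Rectangular cross-sections.** Real filaments from a cylindrical
  nozzle are rounded; the model idealizes them as rectangles. This is a
  deliberate simplification, not checked or corrected.
* **Linear elasticity.** No strain stiffening or viscoelasticity; the
  moduli are small-strain tangent moduli (see below).
* **Zero-spacing limit.** With `s1 = s2 = 0` both expressions collapse
  to the Voigt rule of mixtures `(VL1 E1 + VL2 E2)/VB`, so `gamma = 1`
  for a single material — a useful sanity anchor.

### Off-axis anisotropy

When the measurement axes are rotated by `phi` relative to the line
axes (equal spacings in alternating layers assumed), the package's
default form is the modulus-ellipse interpretation

$$\gamma(\phi) = \sqrt{\frac{E_L^2\cos^2\phi + E_T^2\sin^2\phi}
                            {E_L^2\sin^2\phi + E_T^2\cos^2\phi}},$$

chosen because it is the only reading of the squared-moduli form that
preserves $\gamma(0) = E_L/E_T$; it also satisfies $\gamma(45^\circ)=1$
and $\gamma(\phi)\,\gamma(\phi+90^\circ)=1$. A `linear_mix` alternative
(interpolating the moduli rather than their squares) is available via
the `form` argument; both agree at 0, 45 and 90 degrees, where the
fixed points are forced by symmetry.

### Measurement-side reductions

`modulus_from_curve()` fits an ordinary-least-squares fourth-degree
polynomial to a stress-strain curve and evaluates its derivative at 5%
strain (configurable). Degree 4 needs at least five points; fewer is an
error, not a silent fallback.

`fit_spanning_model()` captures the printability limit of cellular
infill: a line spanning the gap between lines of the layer below
narrows by cohesion, and the relative width `w1/w0` is modelled as a
full bivariate quadratic in the normalized height `h/d` and spacing
`s/d`, fitted by OLS (six coefficients; six points in general position
interpolate exactly). Predictions are clamped to [0, 1]. Because the
published criterion is stated both as a bound on `w1/w0` and on `w1/d`
(they coincide when the unreduced width equals the nozzle diameter),
`is_printable()` exposes both, with `w1/d >= 0.5` as the default
threshold.

### Inverse design

`design_voxel()` inverts the forward model: given a target `gamma`,
the nozzle diameter and the materials, it searches `h1`, `h2` and the
common spacing `s` (any of which may be pinned). Widths are pinned to
the nozzle diameter — the flow-controlled operating point — and
spacings of alternating layers are kept equal, which reduces the space
to three dimensions. The search is deterministic: secondary free
parameters scan a fixed 9-point grid (taller layers first, since fewer
layers means shorter print time), and the primary parameter is solved
by bisection, exploiting monotonicity of `gamma` along each axis
(property-tested). Heights default to [0.2 d, 1.25 d] and spacings to
[0.1 d, d]; a spanning-model constraint restricts candidates to the
printable region. Infeasible targets raise a structured error carrying
the achievable `[gamma_min, gamma_max]`.

## Conformal geometry

The part is printed on a nonplanar substrate with a 3-axis gantry, so
layers are *vertical* offsets of the bottom template rather than
normal-direction offsets. That choice matches the kinematics (the
nozzle moves in z only) and pushes the residual error into the local
inclination, which is then compensated per waypoint:

$$h = \frac{h_0}{\cos\alpha} \pm \frac{d}{2}\tan\alpha,$$

with the plus branch when travelling downhill and minus uphill (the
convention is exposed as a switch, since printhead geometry could flip
it). Volumetric flow is slaved to the commanded speed so the deposited
filament keeps width `d` and height `h`: `Q = v d h`. Accuracy is
known to degrade above ~45 degrees of inclination; the package does not
attempt 5-axis kinematics (out of scope).

Supporting operations and their numerical choices:

* `reorient_min_height()`: principal-axis candidate accepted only when
  it strictly lowers the z-extent, then an exhaustive 1-degree grid
  over both tilt angles in ±45°. Ties prefer the smallest total tilt,
  making the operation idempotent.
* `split_top_bottom()`: a vertex is "bottom" iff its area-weighted unit
  normal has `nz < 0` (threshold configurable); near-vertical normals
  (|nz| < 1e-6) go to the top set and are counted in a warning; faces
  follow the majority of their vertices.
* `heightfield_from_points()`: Delaunay triangulation (Bowyer–Watson)
  with barycentric linear interpolation onto a regular grid; cells
  outside the convex hull are `NA` and poison downstream projection
  with a precise error. Linear fields are reproduced exactly; curved
  surfaces obey the usual `h^2/8 max|f''|` bound, which the tests
  assert.
* `layer_contour()`: iso-contour of the vertical signed distance
  between the mesh and the layer surface, chained into closed CCW
  polygons; open chains (from non-watertight meshes) are dropped with a
  warning rather than silently closed.
* `path_gradient()`: central differences on the horizontal arclength
  (one-sided at the ends); `alpha = atan|dz/ds|`, ascending where z
  increases. Duplicate consecutive waypoints are an error, because they
  would make the finite difference ill-defined.

## Fiber-aligned toolpathing

Each layer is discretized into square grid units carrying a local fiber
angle (from `langer_field()` or a CSV map; imaging-derived collagen
maps are emulated, not processed — the generators produce constant,
random and smooth sinusoidal fields). Every unit is filled with
parallel lines at its angle, pitch `spacing`, the family anchored so a
line passes through the unit centre; the unit's lines are chained into
one serpentine pass, which *is* the naive per-unit toolpath.

Cross-unit continuity follows the generation order (row-major from the
lower-left): free serpentine endpoints of the already-built left and
bottom neighbours that lie on the shared border act as seed points for
the next unit. The unit's line family is shifted along its normal by
the residual offset to the nearest outermost line — at most half the
pitch by construction — so that one line starts exactly at the seed
point, and the serpentine is oriented to begin there. Remaining border
endpoints snap to each other within half the line spacing (greedy
nearest matching, each endpoint used once); unequal line counts simply
leave unmatched endpoints as degree-1 nodes. Junctions are represented
as coincident node pairs joined by a zero-length edge, so each unit
keeps its exact waypoint budget (an 8×8 grid at 10 waypoints per unit
has exactly 640 nodes).

`trim_to_contour()` removes nodes strictly outside the layer polygon
and clips crossing edges with an inserted boundary node.

### The path-count optimizer

Printing each unit separately costs one start-stop extrusion event per
unit. `optimize_paths()` reduces the number of distinct paths with a
restarted randomized heuristic: draw a random untraversed seed
waypoint; extend it forward to the longest reachable continuation,
exploring branches depth-first (bounded exhaustive search with an
explicit stack and a 20,000-expansion budget per seed; the best path
found wins on exhaustion); extend likewise in reverse from the seed;
retire the traversed waypoints; repeat until the pool is empty. The
whole pass restarts `restarts` times (default 100; one RNG permutation
per restart, in order) and the decomposition with the fewest paths is
kept — ties broken by fewest direction reversals, then first found.
The naive decomposition is always included as a candidate, so the
optimizer can never lose to no optimization. On graphs of up to 12
nodes the result is within one path of the exhaustive-search optimum
(property-tested against a subset-DP oracle), and identical inputs give
identical outputs.

### The benchmark and its operationalization

The published benchmark compares naive and optimized path counts on
random-orientation grids with 10 waypoints per unit, where the naive
8×8 decomposition is 64 paths of 10 waypoints. Ten waypoints per unit
is a coarse abstraction — one print line per unit — so the benchmark
generator uses line spacing equal to the unit size (the single
centre-line regime) with the snapping tolerance at half that spacing.
Under these conditions (`make_benchmark_suite()`: sizes 4×4 to 12×12,
5 replicate seeds, 100 restarts) the mean reduction in distinct path
count is roughly 50% and approximately size-independent, and on the
8×8 grid roughly three quarters to four fifths of all waypoints end up
in merged paths. "Merged" is operationalized as *paths strictly longer
than the 10-waypoint single-unit baseline*, since "more continuous
toolpaths" has no formal published definition; the coverage figure is
sensitive to this choice and should be read with it in mind.

What the synthetic benchmark does and does not show: random per-unit
orientations are the hardest case for continuity (real collagen maps
are smooth, so real fields merge more), but the generator has no
imaging noise, no missing data, and perfectly square units. Passing
benchmarks here validates the algorithmic pipeline, not the behaviour
on imaging-derived orientation maps.

## Capsule payloads

Fluid-filled capsules (e.g. blood mimics) embedded in a sacrificial
carrier gel are planned arithmetically. A capsule of radius `rc` (µm)
has volume `vc = (4/3) pi rc^3` (µl); counts for a target volume
fraction `f` use the gel-referenced convention by default — capsules
are loaded on top of a solidified gel, so the capsule volume is
`carrier · f/(1-f)` — with the suspension-referenced alternative
(`carrier · f`) selectable. Counts are floors, so the realized fraction
never exceeds the target. Contact diameters from plate-compression
traces are the largest gap at which force first exceeds the pre-contact
baseline by a threshold, defaulting to five times the pre-contact noise
SD estimated from the first quarter of the trace.

## Pipeline assembly and determinism

`plan_print()` composes the stages per layer: optional reorientation
and bottom-template extraction from the part mesh, conformal layering,
per-layer line generation (successive infill layers rotate the
orientation field by 90°; cover and sacrificial layers use full infill
at the nozzle pitch with alternating 0°/90° direction), contour
trimming, path optimization (layer-indexed seeds derived from the
master seed), projection, gradient, nozzle-height compensation, flow,
and emission with non-extruding travel moves between paths. Commanded
z includes the height compensation relative to the nominal layer
height; per-segment flow uses the mean compensated height of the
segment's endpoints, so total commanded volume equals filament
cross-section times line length exactly on flat parts (tested to 1e-9,
spec'd to 1%).

Everything downstream of a seed is deterministic: fixture generators
save and restore the caller's RNG state, the optimizer's stream order
is documented, and replanning with an identical configuration is
byte-identical — including the written G-code, which stores numbers at
a fixed 6-decimal precision precisely so that the round-trip through
`read_machine_program()` is exact.

Problem sizes used by the test suite and the acceptance script — grids
up to 12×12 units (1,440 waypoints), meshes up to 41×41 vertices, 100
optimizer restarts, 5 replicate seeds — are the package's default
study conditions, chosen to exercise every code path at full fidelity.

## Known limitations

* The voxel model is linear-elastic and rectangular-section; no
  strain-stiffening, no finite-element validation.
* Conformal layering is z-offset only; above ~45° local inclination
  the deposition model is out of its validated range.
* The path optimizer is a heuristic; the minimum path cover problem is
  NP-hard and only small instances are verified against the exact
  optimum.
* `layer_contour()` assumes the mesh closes around the layer surface;
  open shells yield open chains, which are reported and dropped.
* The G-code dialect is self-defined (no firmware standard is targeted)
  and carries flow in a structured comment.
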