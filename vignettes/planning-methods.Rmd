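---
title: "Geometric planning of glenoid baseplate rotation and bi-cortical screws"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometric planning of glenoid baseplate rotation and bi-cortical screws}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The planning problem

In reverse total shoulder arthroplasty (RTSA) the glenoid-side baseplate
(metaglene) is fixed with a central peg and peripheral locking screws. In
small glenoids — common in Asian populations — only the superior and
inferior screws find bone, so fixation hinges on maximizing the bi-cortical
length of those two screws. Three planning variables control them:

* the **glenoid roll angle (GRA)** — rotation of the baseplate about its
  central peg, measured between the glenoid axis (supraglenoid tubercle
  through the plate center) and the superior–inferior screw-hole chord,
  anterior positive;
* per screw, a **cranial–caudal angle (CCA)** and an
  **anterior–posterior angle (APA)** relative to the peg axis (cranial
  positive for the superior screw, caudal positive for the inferior screw;
  posterior positive for both APAs).

`glenplan` implements the full planning pipeline on triangle meshes: bone
modelled as a watertight surface, the baseplate seated by explicit rules,
screws as rays, and bi-cortical length as a ray–mesh intersection problem.
It then reproduces the study-level validation experiment: per-case optima
(the patient-specific or PSI model) are compared against re-evaluating every
case at the cohort's calculated-average (CA) and rounded-average (RA,
nearest 5 degrees) angle prescriptions, with paired t-tests.

## Bi-cortical length as ray casting

A screw is a ray from its hole origin on the baseplate plane into bone. The
mesh is a union of closed components; ray–mesh intersections are merged
into inside-intervals per component and unioned. The bi-cortical length is
the distance from the origin to the far end of the bone corridor reachable
from the first entry without crossing a void wider than `void_bridge_mm`.
The default of 0 mm stops the screw at the first exit from bone: a screw
spanning an empty gap has dubious purchase, and the conservative rule is
exactly reproducible. The flag exists because a screw
may legitimately bridge small cancellous voids; it is the package's choice,
not an anatomical claim. Lengths are measured from the hole origin
(`measure_from = "baseplate"`); `"bone_entry"` subtracts the origin-to-bone
gap for tilted seatings.

For a flat plate of thickness $t$ hit at incidence $\theta$, the length is
$t/\cos\theta$; this slab law, hit-parity, and a point-in-solid marching
oracle anchor the ray-casting tests.

## Baseplate placement rules

The plate normal starts at the glenoid surface normal (nominal placement,
minimizing reaming) and is minimally adjusted so residual superior tilt and
retroversion do not exceed 5 degrees; the adjustment clamps the
version/inclination decomposition of the normal in the scapular-body frame,
so a glenoid at $-8^\circ$ version is corrected to exactly $-5^\circ$. The
plate is seated at the most inferior position, its rim flush with the
inferior glenoid margin along the superior axis. Small glenoids are the
study's premise, so a plate wider than the glenoid warns rather than
errors.

Screw directions compose the two angles intrinsically (CCA in the plane of
the peg axis and hole chord, then APA in the orthogonal plane), which
collapses to the closed form
$d = \cos A\cos C\,\hat b + \cos A \sin C\,\hat r + \sin A \,\hat p$
in the baseplate-local frame, so the whole screw pattern rotates rigidly
with the roll angle and the angle to the peg axis is
$\arccos(\cos C \cos A)$. Variable-angle freedom is a cone
(`cone_half_angle`, default 15 degrees) about a nominal hole axis that
diverges 10 degrees from the peg (cranially/caudally). Angles are reported
relative to the *peg*, which is why a 24.7-degree caudal angle is
admissible: it is 14.7 degrees from the divergent nominal axis. The hole
offset (9 mm) and divergence are configuration fields, since implant
drawings rarely publish them.

## The search

The optimizer is an exhaustive grid search — GRA from $-20$ to $20$ degrees
in 1-degree steps, screw angles on a 1-degree lattice inside the cone —
followed by one local refinement pass at 0.25 degrees, with all grids
aligned so coarse and refined lattices nest. Exhaustive search keeps the
dominance property provable: any admissible fixed prescription is a
candidate the optimizer has seen (up to grid resolution), so per-case CA/RA
lengths cannot exceed the PSI length. The objective is lexicographic, as
the protocol states it: roll angle and superior screw angles are chosen
jointly for the longest notch-safe superior screw (the joint re-optimization
per roll candidate is the package's reading; a `gra_coupling = "nominal"`
mode rates roll candidates with screws on their nominal axes instead), then
the inferior screw is maximized at that roll. A `objective = "sum"` mode
maximizing the summed length is available but not default.

Two selection details are deliberate design choices:

* **Plateau ties.** Superior-length differences below `tie_mm` (default
  0.5 mm — below the grid and tessellation resolution and far below
  clinical screw-length increments) are treated as ties of the roll
  search. Tied roll angles are resolved in favor of the longest inferior
  screw, then the smallest |GRA|. On realistic vaults the superior length
  is nearly flat over a wide roll range, and a pure argmax would pick an
  arbitrary plateau lump; the tie rule makes the choice surgically
  sensible and keeps the inferior screw from being sacrificed for
  sub-resolution superior gains. Remaining ties break toward smaller
  deviation from the nominal hole axis, then the screw's own cranial
  (superior) or caudal (inferior) preference.
* **Dominance guard.** After the cohort averages are known, any case whose
  CA/RA evaluation appears to beat its own optimum (possible only through
  grid resolution) is re-optimized with that prescription as an explicit
  candidate, so the reported PSI solution dominates every fixed-angle
  evaluation it is compared with.

Notch safety treats the suprascapular and spinoglenoid notches as closed
keep-out spheres (default radius 5 mm plus 2 mm clearance) around surface
landmarks; a screw segment, dilated by its radius, tangent to the inflated
sphere is unsafe. Clinical reporting treats notch perforation as a binary
outcome, which a sphere test captures.

## The synthetic scapula and what it does (not) show

No real scapula meshes ship with the package; the cohort is synthetic and
parametric, with analytic ground truth. Each scapula is a constructive
union of closed solids, all in millimetres:

* an elliptical **glenoid disc** (AP width × CC diameter, default
  28.2 × 38.0) tilted by version and inclination relative to a pinned
  scapular-body plane;
* a **vault corridor**: a funnel (entrance radius 0.32 × AP width)
  narrowing to a neck, then a spine-base segment that doglegs posteriorly
  (default 14 degrees) and cranially and tapers into a conical tip at the
  spine confluence. The dogleg makes the corridor non-convex and the
  slender tip rewards near-axial arrival, so achievable length genuinely
  depends on entry point and direction — the phenomenon the planning
  protocol exploits. Without such curvature any straight corridor rewards
  maximally offset entries (the longest chord of a convex body from a
  moving entry point grows with eccentricity), which no tuning can fix;
* a **body pillar** modelling the lateral pillar toward the inferior
  angle: a thin elliptical plate (default 6.5 mm thick, 20 mm wide) with
  its own caudal dogleg and tip;
* a **spine slab** carrying the two nerve-notch landmarks on its surface,
  and two small marker blocks for the trigonum spinae and inferior angle.

The trigonum and inferior-angle markers are pinned to the construction
body plane, so the frame measured from landmarks reproduces the
construction frame exactly and version/inclination recovery is analytic
rather than approximate. Landmarks (supraglenoid tubercle, inferior
glenoid margin, 12 rim points, body landmarks, notch centers) are emitted
at their construction positions; the landmark JSON is the sole source of
anatomical orientation, since mesh files carry none.

The cohort sampler draws gender-stratified anatomy (female AP
$\sim N(27.5, 3.9^2)$, male AP $\sim N(31.1, 5.2^2)$, female CC
$\sim N(37.1, 4.3^2)$, male CC $\sim N(41.1, 4.3^2)$, version
$\sim N(-4.1, 4.6^2)$ truncated at the exclusion bounds, age
$\sim N(73.5, 7.6^2)$ within 51–92 years, 74.4% female). Truncation
replaces post-hoc filtering so the analyzed n stays fixed. Corridor and
pillar lengths are coupled to glenoid size (about +0.6 mm and +0.5 mm per
millimetre of AP width), which reproduces the positive correlation between
AP width and achievable screw lengths; corridor/pillar directions and
entry anchors are jittered (SDs of 1.5–4 degrees and 0.6–0.8 mm) to create
the between-patient heterogeneity that drives the validation experiment.
A `spread` multiplier scales every SD; at `spread = 0` the cohort is
homogeneous and the PSI–CA gap collapses to zero, a limit the tests check.

What passing tests on this cohort do **not** show: real vaults have
continuous cortical/cancellous density (we model solid bone with a binary
in/out rule), real corridors are not piecewise frustums, pathology (Walch
B2/B3/C erosion) is excluded by design, and the roll-angle landscape of
real bone may be sharper or flatter than the synthetic plateau. The
dominance property and the direction of the PSI-vs-average comparison are
structural (they hold for any geometry); the sizes of the gaps are
model-dependent.

## Numerical choices

Meshes are validated combinatorially (every undirected edge shared by
exactly two faces, every directed edge unique, no zero-area triangles);
STL soups are welded at $10^{-6}$ mm before validation. Ray–triangle hits
use Möller–Trumbore with slightly inclusive barycentric bounds; grazing
hits of equal crossing sense within $10^{-9}$ mm are counted once. Screw
origins lying exactly on a surface are nudged $10^{-4}$ mm along the ray
(and the nudge added back) so on-surface origins classify as inside.
Tessellation is controlled by a target circumferential edge length
(default 1.5 mm); walls and caps are planar and therefore exact at any
resolution, so the dominant error is the circumferential sagitta
(about 0.03 mm at default settings). Default problem sizes — 133 cases,
roughly 30 000 candidate rays per case against a 1–2 thousand triangle
mesh — run in about a minute on a single core.

The generator's analytic primitives (elliptical cylinders, circular
frustums, oriented boxes) support exact ray intervals, so the same search
can be run against the exact construction solids
(`ground_truth_optimum()`); agreement between the mesh path and the
analytic path within 1 mm is a recovery test, and an exhaustive
0.25-degree search is the oracle for the grid-plus-refinement strategy.

## Statistics

The paired Student t-test and Pearson correlation are implemented from
their formulas (the pipeline's statistics are self-contained and testable
to $10^{-9}$ against reference implementations). Zero-variance paired
differences are flagged as degenerate rather than given a p-value.
Rounding to the nearest 5 degrees rounds exact halves away from zero — a
documented convention; the study's printed averages never hit a tie. Cases
whose fixed-angle evaluation finds no bi-cortical corridor keep a length
of 0 and are flagged (`fixed_angle_failures = "zero"`), or can be dropped.
No multiple-testing correction is applied, matching the emulated protocol;
the paired t-test (not ANOVA) is the default comparison.

## Known limitations

* The roll-angle optimum on wide vaults is weakly identified (a plateau);
  reported GRA scatter is correspondingly wide, which matters when
  comparing GRA summary statistics across cohorts.
* In a fully symmetric straight-corridor scapula the exact argmax sits at
  the roll extremes (convex-chord geometry), not at zero; symmetry is
  checked as mirror-equality of lengths and by angle recovery at fixed
  roll rather than by asserting a zero-roll argmax.
* The inferior screw is maximized at the superior screw's roll angle
  (lexicographic protocol); a fixed prescription evaluated at a different
  roll could in principle exceed it. The plateau tie rule makes this
  unobserved in practice, and the dominance guard would repair it.
* Bi-cortical length is measured along the ray to the far cortex exit;
  screw head seating, thread run-out and metal-to-bone clearance are out
  of scope.
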