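---
title: "Modelling periodontal-ligament effects on mandibular strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling periodontal-ligament effects on mandibular strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(jawstrain)
```

## The model

`jawstrain` solves small-strain, static, linear elasticity on 4-node
(constant-strain) tetrahedra. Every tissue — cortical bone, trabecular
bone, tooth, periodontal ligament (PDL), bone screw — is isotropic and
linear elastic; heterogeneity enters only through per-element Young's
modulus and Poisson's ratio. Adjacent tissues are bonded: region
interfaces share nodes on conforming meshes, which is the shared-node
realisation of a tie constraint. These are strong simplifications of the
real ligament (a fibrous, time- and direction-dependent tissue), but they
are the standard regime for whole-jaw models, and the package's purpose
is precisely to quantify what this simplified ligament representation
does to the predicted strain field.

The question the pipeline answers is comparative: on one mesh, how do
strain regimes change when the ligament's modulus sweeps the published
range (0.07–1750 MPa), or when the ligament is materially removed (its
elements given tooth properties)? Because both models of a comparison
share geometry, loads and constraints, per-element differences are
well-defined and the comparison machinery (`differential_map`) is exact
rather than interpolated.

### Units and frame

Lengths are mm, forces N, moduli MPa (N/mm²), so no conversion factors
appear anywhere; strains are reported in microstrain (με). The anatomical
frame is **X superoinferior, Y anteroposterior, Z mediolateral** — the
unique assignment under which the sagittal, frontal and transverse
anatomical planes correspond to the XY, XZ and YZ tensor shear
components. Shear is stored with the *tensor* convention
εᵢⱼ = ½(∂ᵢuⱼ + ∂ⱼuᵢ); rosette-gauge practice sometimes uses engineering
shear γ = 2ε, so `engineering_shear()` exposes it and every output labels
the convention. The working (chewing) side of the phantom is Z > 0.

## Material calibration

Cortical bone properties come from a linear calibration chain:
density ρ = a + b·GV from grayscale, then ν = c + d·ρ and E = e + f·ρ.
Two numerical guards are needed because straight lines leave the physical
range:

* `E_floor` (default 50 MPa) clamps E from below — the E(ρ) line is
  negative at low density, and a non-positive modulus would make the
  stiffness indefinite;
* ν is clamped into `[v_floor, v_cap]` = [0.05, 0.49] — values ≥ 0.5 are
  not meaningful for an isotropic solid.

One consequence worth knowing: with the default coefficients there is no
density at which E and ν are *simultaneously* in the textbook cortical
range (E ≈ 15 GPa requires densities where the ν line is far below
zero). The phantom's grayscale generator prioritises the stiffness
ordering (cortical ≈ 13–20 GPa > trabecular 10 GPa), so calibrated ν
saturates at the floor; if a larger lateral contraction matters for an
application, raise `v_floor` — all coefficients and clamps are fields of
`calibration_model()`.

Heterogeneity is quantised into `n_bins = 80` **equal-width** density
bins over the observed density range, each represented by its midpoint
(`assign_cortical`). Equal-width was chosen over equal-count because it
makes the quantisation error bound trivial (half a bin width in ρ, times
|f|, in E) and keeps binning independent of the density histogram. A
constant grayscale field therefore yields exactly one material, and
`n_bins = 1` assigns the mid-range density everywhere.

The density line is read as an *affine* map ρ = a + b·GV (intercept
−0.01979662, slope 1.0577433). Read as a literal product of two constants
and GV it would give negative density for every positive grayscale value;
calibration lines are conventionally affine, matching the ν and E lines.
Both coefficients are configurable for users whose scanners are
calibrated differently.

Fixed tissues: teeth E = 24500 MPa, ν = 0.49; trabecular 10000 MPa,
0.30; screws 105000 MPa, 0.36. Ligament variants all use ν = 0.49 and
E ∈ {0.68 (baseline), 0.07, 0.18, 13.8, 1750} MPa, plus `NO_PDL`
(= tooth properties: material removal with preserved geometry).

## Loading and constraints

Each of the ten jaw-elevator muscles (working/balancing superficial and
deep masseter, anterior and posterior temporalis, medial pterygoid)
contributes a force of magnitude PCSA × specific tension × EMG scale,
with specific tension 30 N/cm². The direction runs from the centroid of
the muscle's mandibular insertion node set toward its cranial origin
point, and the total is split **equally** over the insertion nodes. Equal
splitting is the simplest rule whose total is independent of how the
insertion is partitioned; area-weighted splitting would be the natural
refinement but changes nothing about the comparisons, which share loads
exactly.

Chewing constraints: the occlusal node sets of the working-side bite
teeth are fixed in all three directions (bite force then *emerges* as the
reaction at those nodes rather than being prescribed); one node at the
top of the working-side condylar post is fixed in X, Y and Z; the
balancing-side condylar node is fixed superoinferiorly and
anteroposteriorly but left free mediolaterally, which permits lateral
transverse bending of the corpus. The `overconstrained` scenario fixes
both condyles fully (a boundary-condition sensitivity probe), and the
`clenching` scenario keeps the chewing constraints but replaces each
muscle's EMG scale from a user table. Constraints act on translational
DOFs of solid elements, so nodal rotation at a single constrained point
remains free by construction.

The default muscle table (`default_muscles()`) carries synthetic PCSA and
EMG values plausible for a macaque-sized jaw (working side more active);
they are generator defaults for exercising the pipeline, not measured
quantities, and a user's own table can be supplied as CSV.

## Solver

Assembly is vectorised: for constant-strain tets the (a,b) node block of
the element stiffness is V·(λ gₐ g_bᵀ + μ g_b gₐᵀ + μ (gₐ·g_b) I) in the
shape-function gradients gₐ. The exported single-element
`element_stiffness()` builds BᵀDB explicitly instead; the two independent
formulations are cross-checked against each other and against a
finite-difference Hessian of the elastic energy in the test suite.

Constraints are applied by row/column elimination, not penalties, so they
are satisfied exactly and reactions are recovered cleanly as K·u − f on
the eliminated rows. The reduced system is solved by sparse Cholesky
factorisation (an implicit direct static solve); a Jacobi-preconditioned
conjugate-gradient solver is available behind `solver = "cg"` (tolerance
10⁻¹⁰) for memory-constrained cases. Every solve logs the relative
residual on the free DOFs and the global equilibrium error (net applied
plus net reaction force); both are ≤ 10⁻⁸ relative in all shipped
configurations, and the test suite enforces that bound.

Verification rests on two analytic problems: a uniaxial patch test (a
traction-loaded box must reproduce the uniform strain state to machine
precision — constant-strain elements represent constant fields exactly)
and a slender cantilever (L/h = 10) checked against the Euler–Bernoulli
deflection PL³/3EI. Constant-strain tets converge slowly in bending, so
the suite fixes the cantilever at 100×10×10 cells (60k tets), where the
tip deflection sits within 5% of beam theory; the refinement study in the
tests confirms monotone convergence toward the analytic value.

## Strain analysis conventions

* ε₁ denotes the maximum principal strain. "ε₂", following gauge usage,
  denotes the **minimum** principal strain: the smallest eigenvalue of
  the 3D tensor for volume elements, and the smaller in-plane principal
  value at a gauge. The package names the latter `e_min`/`e2`
  accordingly.
* Gauge readouts select surface elements whose boundary-face centroid
  lies within the gauge radius of the gauge centre (a deterministic
  stand-in for locating a physical gauge by radiograph overlay), rotate
  each tensor into the gauge frame (rows of the gauge rotation are its
  axes), and report in-plane principal strains and the ε₁ orientation.
* A strain axis is 180°-ambiguous. The reported orientation is the fixed
  representative (½·atan2(2εxy, εxx − εyy)) mod 360, measured
  counterclockwise from the gauge's local +x axis — deterministic, and in
  [0°, 360°) to match polar-histogram reporting of gauge data.
* Region summaries report mean, SD, min, max; SD uses the sample
  convention (n − 1), and the choice is recorded here because summary
  tables in the literature rarely state the divisor.
* Validation verdicts: a model's gauge median passes `within_whiskers`
  if it lies in [Q1 − 1.5·IQR, Q3 + 1.5·IQR] of the in-vivo sample
  (quartiles by linear interpolation between order statistics — R type 7,
  the common boxplot default) and `within_range` if it lies within the
  raw sample range. Orientation comparison is circular: the smallest arc
  covering the model's orientations must lie inside the smallest arc
  covering the in-vivo orientations. The arc rule replaces a visual
  polar-plot comparison with something deterministic.

## The mandible phantom

`make_phantom()` builds a U-shaped curved corpus (structured grid in
arch-length/width/height coordinates, each cell split into six
conforming tetrahedra along a consistent diagonal) with condylar posts at
the posterior ends, per-side tooth sockets, and — when `pdl_thickness ≥
3` — a conforming ligament shell exactly that many element layers thick
(default 3 layers of 0.3 mm) wrapping each tooth block except its
occlusal surface. Three or more layers across the ligament space is the
robust minimum for a non-manifold shell of elements. Structured extruded
meshing was chosen over Delaunay deliberately: determinism and exact
region boundaries matter more here than element quality, and the volume
deficit of chordal cells against the curved solid is bounded and reported
(`volume_tol` attribute).

Key design points, all decided once at generator level:

* `pdl_thickness = 0` builds the *identical grid* and simply labels the
  socket interior as tooth, so the zero-PDL twin is geometry-matched to
  its sibling and material-swap comparisons stay element-to-element. The
  default comparison route is one mesh plus material swap; geometric
  removal exists only as this clearly separate mode.
* The bite set constrains the anterior working-side sockets
  (premolar/first-molar analogues), leaving the most posterior socket
  free on each side.
* The `tooth_root` element set — the region over which the
  stress-shielding comparison is evaluated — contains the apical parts of
  the *unconstrained* teeth. Roots of bite-constrained teeth are excluded
  by design: their occlusal surfaces are displacement-fixed, so with a
  compliant ligament the moving bone drags those roots and bending
  dominates their strain state. That is a boundary-condition artifact of
  the bite idealisation (the same reason condylar constraint points are
  treated as artifact regions), not ligament mechanics. `tooth_root_all`
  is provided for users who want every root.
* The ligament-modulus sweep is summarised over the **global cortical
  surface** element set (every cortical element owning a boundary face).
  The torsional-rigidity prediction concerns global surface strains;
  directly alveolar-adjacent bone shows genuinely mixed ε₁ behaviour
  across the modulus range (local load-transfer effects), so a monotone
  assertion belongs to the global set.
* The torsion comparison (shear strains over the alveolar cortical set)
  is asserted on the mean over the three anatomical shear components;
  individual components can move in opposite directions locally.
* Gauge sites: two on the buccal surface of the working-side corpus below
  the most posterior socket (upper/lower), one lingual — with local z
  along the outward surface normal and local x superoinferior.
* The synthetic grayscale field is a smooth low-order ramp plus bounded
  uniform noise, scaled so calibrated cortical E spans roughly 13–20 GPa
  (see the calibration note above); `constant =` gives a homogeneous
  field for testing.
* Synthetic in-vivo samples are drawn through a piecewise-linear quantile
  function anchored at the planted minimum, quartiles and maximum, so the
  empirical median and IQR converge to the planted values; orientations
  are uniform inside the planted circular arc. Infeasible plants (range
  narrower than the IQR) are rejected.

What the phantom does *not* emulate: real mandibular geometry (curvature
of the corpus is circular, sockets are rectangular boxes, the ramus is a
plain post), realistic muscle attachment footprints, CT imaging physics,
or inter-individual variation. Passing pipeline properties on the phantom
therefore demonstrates that the *machinery* — calibration, loading,
solving, differencing, validation — implements the intended mechanics and
that the qualitative ligament effects (shielding of unconstrained roots,
strain collapse in a stiffened ligament space, global surface-strain
decrease with ligament stiffening, reduced alveolar shear without the
ligament) emerge from linear elasticity on a socketed curved beam; it
does not certify quantitative strain magnitudes for any real jaw.

## Numerical choices and degenerate inputs

* Tet node ordering must give positive signed volume; inverted elements
  are repaired by swapping two nodes (with a reported count), zero-volume
  elements are a hard error naming the element.
* Mesh indices are contiguous and 1-based internally; arbitrary external
  ids are remapped on read (increasing-id order) and written back
  contiguously. Coordinates are serialised with 17 significant digits so
  read→write→read is the identity.
* Boundary faces are found by exact face-key counting (integer keys below
  2⁵³); normals are oriented away from the owning element's centroid.
* The vectorised principal-value path uses the trigonometric closed form
  for symmetric 3×3 eigenvalues with the isotropic case (p → 0) handled
  separately; it is tested against characteristic-polynomial roots.
* Rotations are validated to be orthonormal (tolerance 10⁻⁹) before any
  tensor rotation.
* Forces applied along fully-fixed directions of constrained nodes are
  zeroed with a warning (they would be silently absorbed by the
  constraint otherwise).

## Problem sizes

The shipped configurations were sized so the full suite runs comfortably
on a single CPU: the default phantom meshes to ≈57k tetrahedra (≈35k
DOF), the cantilever verification uses 60k tetrahedra, and the
determinism checks use a reduced two-socket phantom (≈27k tetrahedra).
One phantom solve takes a few seconds; the six-variant experiment runs in
about a minute.

## Known limitations

* Linear kinematics: ligament strains under chewing loads reach percent
  level and beyond, far outside the small-strain regime; the linear
  solution is still the intended object of study (the comparisons are
  between linear models), but absolute ligament strains should be read as
  model quantities, not tissue predictions. Hyperelastic or viscoelastic
  ligament models, and dynamic simulation, are out of scope.
* Isotropic cortical bone: directional moduli are not represented; the
  80-bin heterogeneous field captures only scalar stiffness variation.
* Constant-strain elements are stiff in bending; mesh-dependent accuracy
  is quantified by the cantilever benchmark, and conclusions are drawn
  from differences between models sharing a mesh, where discretisation
  bias largely cancels.
* Bite force is not prescribed — it emerges from the occlusal
  constraints — so comparisons across constraint scenarios change the
  effective bite force as well as the constraint pattern.
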