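---
title: "Virtual mitral valve repair: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual mitral valve repair: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`mvrepair` simulates the standard surgical repair of posterior mitral
leaflet prolapse — quadrangular resection with annular plication and
ring annuloplasty — on a dynamic finite-element model of the valve, and
quantifies how the repair changes leaflet stresses, chordal loads,
annular dimensions and coaptation. This vignette explains the models the
package implements, the parameters that matter, what the synthetic valve
generator does and does not emulate, and the design decisions taken
where several reasonable choices existed.

## The modeled system

The mitral valve is modeled as two thin anisotropic membranes (anterior
and posterior leaflets) attached to a saddle-shaped annulus, tethered to
two fixed papillary muscle tips by tension-only chordae tendineae, and
loaded by the transvalvular pressure difference on the ventricular side.
During systole the pressure difference rises to about 15.4 kPa, the
leaflets billow toward the atrium and — in a competent valve — seal
against each other along a coaptation zone. Rupture of the marginal
chordae of the middle posterior scallop (P2) removes the tethering
there: the unsupported segment everts past the annular plane (flail),
coaptation is lost centrally, and the neighboring intact chordae pick up
the abandoned load.

The surgical repair emulated here removes a quadrangular portion of the
flail P2 segment between two excision curves that run from the annulus
to the free margin, sutures the cut edges together along a smooth spline
(plicating the posterior annulus), and then fixes the annulus to a
downsized prosthetic ring.

## Constitutive models

**Leaflets.** Each leaflet is a Fung-type anisotropic hyperelastic
membrane with strain energy per unit reference volume

$$ W = \tfrac{c}{2}\left(e^{Q} - 1\right), \qquad
   Q = a_{cc} E_{cc}^2 + a_{rr} E_{rr}^2 + 2 a_{cr} E_{cc} E_{rr}
       + a_{ss} E_{cr}^2, $$

with in-plane Green strains in the local fiber frame (circumferential
and radial directions stored per element). Positive semi-definiteness of
the quadratic form (`a_cc a_rr >= a_cr^2`) is enforced at construction
so the energy is convex near the reference state. The second
Piola–Kirchhoff stress is the exact gradient `S = dW/dE`; the test suite
verifies the closed form against central-difference gradients of `W` to
1e-6 relative everywhere it is sampled. Because the shear exponent is
rarely reported, `a_ss` defaults to `(a_cc + a_rr)/2`.

The numeric coefficients shipped as defaults (anterior
`c = 8 kPa, a_cc = 35, a_rr = 20, a_cr = 10`; posterior
`c = 6 kPa, a_cc = 30, a_rr = 18, a_cr = 8`) are editable plausible
values for valve tissue — anterior stiffer than posterior,
circumferential stiffer than radial, working strains of 10–20% at
systolic membrane tensions. They are deliberately *not* presented as a
fit to any specific experiment; `fit_fung_params()` exists to replace
them whenever biaxial stress–strain data are available, and recovers
known parameters to better than 1% from noiseless synthetic data.

**Chordae.** Each chorda is a tension-only cable with an incompressible
uniaxial Ogden response,
$\sigma(\lambda) = \sum_p \mu_p (\lambda^{\alpha_p} -
\lambda^{-\alpha_p/2})$ for $\lambda \ge 1$ and zero in compression — a
slack cable carries no load. Axial force is $\sigma(\lambda)$ times the
reference cross-sectional area (0.29 / 0.27 / 0.61 mm² for anterior
marginal, posterior marginal and strut chordae). Defaults
(`mu = 600 kPa, alpha = 12` marginal; `450 kPa, 10` strut) give chordal
strains of 5–15% under physiologic loads.

**Tissue constants.** Thickness 0.69 mm (anterior) / 0.51 mm
(posterior), density 1100 kg/m³, Poisson ratio 0.48. Near-
incompressibility enters the membrane kinematics through the thickness
stretch $\lambda_t = J_{\text{in-plane}}^{-\nu/(1-\nu)}$, which affects
the reported Cauchy stresses.

**Units.** Internally everything is mm–mg–ms, a consistent system in
which stress is exactly kPa and force exactly mN; this keeps numbers
near unity at valve scale and avoids catastrophic cancellation.

## The dynamic solver

Explicit central-difference dynamics over total-Lagrangian
constant-strain triangles (membranes: no bending stiffness, the standard
desk-scale simplification for valve leaflets), with:

- *Follower pressure*: the transvalvular waveform acts along the current
  element normals on the ventricular face. The default waveform rises
  from 0 at end diastole (t = 0, the open configuration surgery operates
  on) to 15.4 kPa at peak systole (t = 250 ms), dips to −2.9 kPa in
  diastole, over an 800 ms cycle; only the two extrema are measured
  quantities, the shape between them is replaceable via a two-column
  CSV.
- *Prescribed annular motion*: annulus nodes follow
  `x(t) = x_sys + g(t) (x_dia - x_sys)` along fixed per-node direction
  vectors between the gated peak-systolic and end-diastolic
  configurations; the gating `g` ships as a smooth default and is
  user-replaceable.
- *Contact*: node-to-triangle penalty forces over a two-sided detection
  shell (default 0.8 mm), with Coulomb friction (mu = 0.05) applied as a
  viscously regularized tangential force capped exactly at mu times the
  normal force, and node-to-segment penalties for leaflet–chordae
  contact. Node/triangle pairs already inside the shell in the reference
  configuration (the coincident commissural columns of the two leaflets)
  are permanently excluded — the usual general-contact convention for
  initial overclosures.
- *Damping and mass scaling*: mass-proportional damping
  (default 0.25 /ms) and density scaling (default 100x) make closure
  quasi-static; results are flagged if the kinetic/strain energy ratio
  exceeds 5% at peak load (it is typically below 1e-4).

### Numerical choices

- The timestep defaults to 0.12 times the zero-strain CFL bound. The
  factor is deliberately small: the exponential Fung law stiffens by an
  order of magnitude at working strains, and the contact penalty adds
  stiffness; the margin was sized so that the shipped closure problems
  integrate stably, and the bound scales correctly with mesh refinement
  and material stiffness (verified in tests).
- The contact penalty defaults to `0.0012 m_min / dt^2`, far below the
  penalty-oscillator stability limit while strong enough to keep shell
  penetrations at a fraction of the detection thickness under systolic
  load.
- Energy bookkeeping accumulates external (pressure + constraint-
  reaction) work, damping and friction dissipation, and strain plus
  contact potential; the residual stays well under 2% of peak external
  work on closure runs.
- Degenerate (collapsed) elements are detected through the in-plane
  Jacobian and abort the run with the element id; divergence aborts
  return the last valid state.
- A membrane free margin under compressive load wrinkles through a
  symmetry-breaking buckling bifurcation; which wrinkle pattern is
  selected depends on rounding noise. Mirror symmetry of a symmetric
  closure problem therefore holds in aggregate (median mirror distance)
  and as exact solver equivariance on the mirrored problem, but not
  pointwise at individual wrinkles — the test suite asserts the former.

## The synthetic valve generator

No patient imaging ships with the package, so `build_synthetic_valve()`
constructs a labeled, parametric stand-in for a segmented valve: smooth
tensor-product leaflet patches lofted from a saddle annulus to a
parametric free-margin curve, Carpentier regions (A1–A3/P1–P3) assigned
by thirds of the intercommissural angle, per-element fiber frames,
free-margin marginal chordae spaced uniformly by arc length, and two
anterior strut chordae.

The default parameters describe one particular anatomy: a dilated,
prolapse-prone valve with A-P diameter 43 mm and intercommissural
diameter 37 mm, a posterior annular bulge (6.5 mm, 0.30 rad wide)
centered on P2 — the asymmetric annular dilation that accompanies
posterior prolapse — and a redundant, billowing posterior leaflet
(16 mm tall, steeply hanging, with a 3 mm three-lobed scalloped margin
undulation). These choices were made once, at design time, so that the
published surgical protocol is geometrically feasible on the synthetic
twin: with 16 marginal chordae per leaflet and a 70% central P2 chordal
rupture, the chordae-free flail gap is wide enough to admit
annulus-to-margin excision curves kept 5 mm clear of every remaining
intact insertion. The post-plication annular dimensions are *outputs*
of the pipeline run on this anatomy, not assigned values.

What the generator does **not** emulate: real segmentation noise and
imaging resolution, patient-specific papillary positions (tips are
placed parametrically below the commissures), chordal branching fans
(each cable stands for a fan), annular tissue mechanics (the annulus is
kinematically driven), and any inter-patient variability. Passing tests
on the synthetic twin therefore demonstrate that the *method* behaves
correctly and reproduces the published repair behavior on a comparable
anatomy — not that any individual patient's stresses are predicted.

## Virtual surgery

- `plan_resection()` finds the two excision curves as shortest
  annulus-to-margin paths in the leaflet edge graph, biased to constant
  intercommissural angle, choosing the widest quadrangle whose curves
  stay at least the chordal margin (Euclidean, brute-force audited) from
  every remaining marginal insertion. The quadrangle is bounded by
  annulus, free margin and the two curves.
- `excise()` removes the elements, drops orphaned nodes and the chordae
  inserting on them, and reindexes; the curves become boundary paths.
- `suture_target_curve()` pairs the two cut edges by normalized arc
  length, takes pair midpoints (equidistant from both generators by
  construction) and interpolates them with a natural cubic spline.
- `plicate_and_suture()` builds the kinematic displacement program: cut
  edges ramp onto the suture curve, the posterior annulus redistributes
  along a commissure-anchored, depth-scaled copy of its remaining
  (wedge-excised, spline-bridged) arc whose length equals the remaining
  annular material, and the anterior annulus is held exactly fixed.
  Interior nodes follow by harmonic (graph-Laplacian) interpolation of
  the boundary displacements, and paired nodes merge into a watertight
  suture line. The geometric program is applied directly — annular
  measurements are determined by the prescribed boundary motion either
  way — and the damped dynamic solver then settles the leaflets under
  load in the post-repair simulation.
- `size_ring()` implements the deterministic sizing rule: the largest
  catalog size strictly below the smallest of the intercommissural
  measurements (and the anterior-leaflet width when supplied). With the
  gated pair 37/35 mm this selects the 34 mm ring.
- `ring_profile()` reconstructs a saddle ring as a periodic cubic
  spline through canonical control points scaled to the size label:
  septolateral extent 0.75x the intercommissural extent, peak-to-peak
  saddle height 10% of the size, with an accentuated anterior peak.
  These catalog proportions are editable; exact manufacturer geometry
  is not public.
- `implant_ring()` rigidly aligns the ring axes with the annular
  landmark axes and maps annulus nodes to ring points at matching
  normalized arc length, anchored at the commissures. Arc-length (not
  nearest-point) correspondence avoids the fold-over that nearest-point
  mapping produces on strongly remodeled annuli. Thereafter the annulus
  is fixed to the ring, overriding annular motion.

### Resolved open choices

- *Prolapse selection*: the ruptured set is the centrally contiguous
  block of the scallop's marginal chordae (`floor(fraction x n)`),
  mirroring the clinical picture of a contiguous ruptured segment
  flanked by intact chordae; a seeded random subset is available.
- *Chordal margin semantics*: the 5 mm margin is enforced against the
  chordae remaining after rupture; with the contiguous central rupture
  the feasible excision band lies inside the chordae-free gap, so no
  intact chordae are sacrificed.
- *Table conventions*: paired chordal stresses are time averages over
  the systolic plateau (pressure at or above 90% of peak), and percent
  changes are reported rounded to integers.
- *Stress scalar*: the reported field is the maximum in-plane principal
  Cauchy stress (von Mises available via an argument); "peak systole"
  is operationally the time of maximum transvalvular pressure.

## Problem sizes and runtimes

The shipped experiments use deliberately desk-scale meshes: the default
patient twin has 896 triangles (528 nodes), the fast test valve 224
triangles. A 250 ms closure to peak systole integrates in roughly half a
minute to two minutes on one CPU at these sizes; the full pre/post
repair experiment (two closure simulations plus surgery and metrics)
completes in a few minutes. Mesh resolution, durations, mass scaling and
damping are all configuration, so the same pipeline scales up when
higher fidelity is wanted.

## Known limitations

- Membrane elements carry no bending stiffness: wrinkling patterns are
  noise-selected and compressive buckling is under-resolved.
- The pressure is prescribed, not computed — no fluid–structure
  interaction and no regurgitant-jet hemodynamics.
- Papillary tips are fixed in space; papillary dynamics and chordal
  branching are not modeled.
- The annulus is kinematically driven, so annular reaction forces are
  not meaningful outputs.
- Viscoelasticity, tissue growth/remodeling and damage are out of
  scope; reported stresses can be compared against failure thresholds
  but failure itself is not simulated.
- Absolute stress magnitudes inherit the uncertainty of the default
  constitutive coefficients; pre-versus-post *comparisons* on the same
  anatomy are the robust outputs.
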