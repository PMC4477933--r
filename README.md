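# mvrepair

Virtual mitral valve (MV) repair simulation in R: quadrangular
posterior-leaflet resection with annular plication, annuloplasty ring
sizing and implantation, and explicit dynamic finite-element simulation
of valve closure, before and after repair.

## Who this is for

Cardiovascular biomechanics researchers and computational-surgery
developers who want a desk-scale, fully scriptable implementation of the
personalized MV repair simulation workflow: build (or import) a labeled
valve model with chordae, induce P2 chordal rupture and prolapse,
perform the virtual surgery, run dynamic closure, and quantify what the
repair changed — leaflet stress fields and regional averages, chordal
stresses, annular dimensions and coaptation lengths.

## The models at the core

* **Leaflets** — Fung-type anisotropic hyperelastic membranes,
  `W = (c/2)(exp(Q) − 1)` with
  `Q = a_cc E_cc² + a_rr E_rr² + 2 a_cr E_cc E_rr + a_ss E_cr²` in the
  local circumferential/radial fiber frame; `S = ∂W/∂E`. Thickness
  0.69 mm (anterior) / 0.51 mm (posterior), density 1100 kg/m³, Poisson
  0.48 (near-incompressible thickness update).
* **Chordae** — tension-only Ogden cables,
  `σ(λ) = Σ μ_p (λ^α_p − λ^(−α_p/2))` for `λ ≥ 1`, zero when slack;
  force = `σ · A_ref` (areas 0.29 / 0.27 / 0.61 mm² for anterior
  marginal / posterior marginal / strut chordae).
* **Loading** — transvalvular pressure waveform (peaks +15.4 / −2.9
  kPa) applied as follower loads on the ventricular face; prescribed
  annular motion between gated peak-systolic and end-diastolic
  configurations.
* **Solver** — explicit central-difference dynamics on total-Lagrangian
  constant-strain-triangle membranes, node-to-triangle penalty contact
  with a Coulomb friction cap (μ = 0.05), mass-proportional damping and
  mass scaling for quasi-static closure, with full energy accounting.
* **Surgery** — excision-curve planning 5 mm clear of remaining intact
  chordae, element excision, cubic-spline suture target curve through
  pair midpoints, annular plication with the anterior annulus fixed,
  deterministic ring sizing (largest catalog size strictly below the
  smallest intercommissural measurement) and saddle-ring implantation
  by commissure-anchored arc-length mapping.

See `vignettes/virtual-mv-repair.Rmd` for the full account of models,
defaults and design decisions.

## Worked example

```r
library(mvrepair)

# the synthetic "patient": a dilated valve with posterior prolapse
mv <- build_synthetic_valve(ap_diameter = 43, alpm_diameter = 37)
mv
#> valve_mesh: 528 nodes, 896 triangles (end_diastole)
#>   annulus: A-P 43.0 mm, Al-Pm 37.0 mm
#>   regions: A1=168 A2=168 A3=176 P1=126 P2=126 P3=132

ch <- attach_chordae(mv)                       # 16+16 marginal, 2 strut
pr <- induce_prolapse(ch, mv, scallop = "P2", fraction = 0.7)
attr(pr, "removed")
#> [1] "C_7"  "C_8"  "C_9"  "C_10"               # ruptured P2 chordae

# virtual quadrangular resection + plication/suturing
plan <- plan_resection(mv, pr, scallop = "P2", chordal_margin = 5)
plan
#> resection_plan (P2): 60 elements; excision curves 11.6 / 16.9 mm;
#> min chordal distance 5.10 mm
ex    <- excise(mv, pr, plan)
curve <- suture_target_curve(ex$plan$edge_A, ex$plan$edge_B,
                             ex$plan$node_pairing, ex$mesh)
ps    <- plicate_and_suture(ex$mesh, curve, ex$plan, ex$chordae)
round(measure_annulus(ps$mesh), 1)
#>   ap_diameter_mm alpm_diameter_mm
#>             36.7             37.0

size_ring(37, 35)                              # gated Al-Pm pair (mm)
#> [1] 34
```

The A-P annular diameter contracts from 43 mm to 36.7 mm while the
intercommissural distance stays at 37 mm — the plication shortens the
posterior annulus only, since the anterior annulus is held fixed. The
34 mm ring is then reconstructed with `ring_profile(34)` and implanted
with `implant_ring()`.

Dynamic closure and the pre/post comparison:

```r
sim_pre  <- simulate_closure(mv, pr, motion = annular_motion_from_mesh(mv))
imp      <- implant_ring(ps$mesh, ring_profile(size_ring(37, 35)))
sim_post <- simulate_closure(imp$mesh, ps$chordae)

max(stress_field(sim_pre)$stress_mpa)    # peak leaflet stress, pre
max(stress_field(sim_post)$stress_mpa)   # ... and post-repair
regional_average_stress(stress_field(sim_post))
coaptation(sim_post)
chordal_stress_table(sim_pre, sim_post)
```

On the shipped synthetic twin the repair lowers the peak leaflet stress
by about a factor of three, the largest regional stress decrease is in
P2, central (A2-P2) coaptation is restored from zero, and every
neighboring intact chordal stress falls — the full comparison runs as
the acceptance test suite.

A thin command-line driver wraps the whole protocol:

```sh
Rscript inst/cli/mvrepair.R pipeline --seed 1 --out run1
```

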