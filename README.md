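# airwaycollapse

Nonlinear finite-element simulation of exhalation-driven tracheal collapse
in tracheomalacia (TM).

TM — excessive collapse of the trachea during exhalation — is attributed to
weakened cartilage rings and/or a weakened posterior trachealis muscle, but
neither the degree of property loss nor the malacic segment length that tips
an airway from narrowing into life-threatening collapse can be measured in
patients. `airwaycollapse` builds idealized pediatric trachea models
(semicircular cartilage/fibrous arch, flat trachealis muscle, mucosal
lining; 6–10 mm lumen diameter, 50 mm length), loads them with exhalation
pressure from 0 to 40 cm H₂O, and quantifies collapse so that malacic
length, severity and diameter can be swept systematically. Severe collapse
emerges as a **snap-through instability** of the weakened anterior arch —
a limit point on the load–deflection path — while posterior muscle
weakening produces gradual, stable infolding.

The pieces, each usable on its own:

* **Constitutive model.** Isotropic Ogden hyperelasticity in principal
  stretches, `W = Σ (a/b)(λ̄₁ᵇ + λ̄₂ᵇ + λ̄₃ᵇ − 3) + ½κ(ln J)²`, with the
  incompressible uniaxial closed form `σ(λ) = Σ a(λᵇ − λ^(−b/2))`;
  least-squares coefficient fitting with multistart (`fit_ogden()`, with
  `tidy()`/`glance()` methods), and a built-in library for tracheal
  cartilage (a = 0.109 MPa, b = 16.63), fibrous tissue (0.01, 11.05),
  trachealis smooth muscle (0.08, 6.29) and mucosa (0.1, 3.4).
* **Geometry.** Parameterized all-hexahedral trachea meshes with tissue
  region labels, centered anterior (1/3/5/7 rings ≙ 2/8/14/20 mm) and
  posterior (2–32 mm) malacic element selection, luminal surface and
  mid-length cross-section extraction, VTK export.
* **Solver.** Total-Lagrangian Newton solver with exact spectral Ogden
  tangents, selective reduced volumetric integration, follower pressure,
  frictionless penalty self-contact, adaptive load stepping, and arc-length
  continuation (Crisfield or single-dof control) through limit points.
* **Collapse analysis.** Lumen area-ratio curves calibrated to the intact
  lumen, pressure↔force conversion (1 cm H₂O = 98.0665 Pa), an
  instability-onset detector (first point falling more than δ below the
  linear extrapolation of the two previous force–area-ratio points), wall
  strain summaries, and sweep drivers over diameter × severity × extent.
* **Synthetic data.** Generators for uniaxial stress–strain curves from the
  Ogden closed form (the original preterm-lamb source data are not publicly
  deposited), plus single-element, thick-ring and shallow-truss benchmark
  fixtures with solver-independent analytic oracles.

## Worked example

Weaken the seven central cartilage rings (a 20 mm malacic segment) of a
10 mm trachea to mucosa properties and exhale to 40 cm H₂O:

```r
library(airwaycollapse)

mesh <- build_trachea_mesh(trachea_config(diameter = 10, n_arc = 12,
                                          n_chord = 6, n_wall = 1))
res  <- run_load_program(mesh,
                         malacia = malacia_spec("anterior", "mucosa", rings = 7),
                         program = load_program(max_pressure = 40),
                         config  = solver_config(ds_min = 0.1, max_iter = 15))
curve <- area_ratio_curve(res)
print(as.data.frame(curve), digits = 3)
detect_instability(curve, termination = res$termination)
max_wall_strain(res, 2)
```

```
  pressure_cmh2o force_n area_ratio
1            0.0   0.000      1.000
2            4.0   0.503      0.873
3            8.0   1.007      0.698
4           12.0   1.510      0.508
5           16.0   2.013      0.315
6           16.8   2.117      0.258
<instability_report> onset at step 6: 16.8 cm H2O, 2.12 N (deviation NA)
[1] 0.573
```

The run terminates as `non_convergence_collapse`: past ≈2.1 N no nearby
equilibrium exists under load control — the weakened arch snaps through,
with wall strains at 2 N already at 57%. Arc-length continuation
(`solver_config(continuation = "arc_length")`) follows the fold into wall
contact. An intact 6 mm model instead descends nearly linearly to
40 cm H₂O with no onset, and posterior-muscle weakening
(`malacia_spec("posterior", length_mm = 32, a = 1, b = 1)`) reduces the
area gradually with no instability — the three regimes the analysis is
built to separate. (The intact 10 mm model reaches its own ring-buckling
limit near 24 cm H₂O, ≈3 N — classical `3EI/R³` theory puts the critical
pressure of the 5 mm-radius cartilage arch at ≈28 cm H₂O, with the 8 and
6 mm models safely beyond the 40 cm H₂O range; larger airways really are
more collapse-prone.)

`autoplot(curve)` draws the area-ratio curve; `run_sweep(anterior_sweep_grid())`
reproduces the full diameter × severity × ring-count panel.

## References

The model targets the collapse phenomenology of computational TM studies in
the pediatric airway literature: Ogden tissue fits to preterm-lamb tracheal
data, idealized ring/gap trachea geometry, exhalation pressures to
40 cm H₂O, and snap-through as the mechanism separating severe from
mild/moderate TM.
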