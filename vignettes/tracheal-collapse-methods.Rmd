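---
title: "Modeling exhalation-driven tracheal collapse: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling exhalation-driven tracheal collapse: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airwaycollapse)
```

## The scientific question

Tracheomalacia (TM) is excessive collapse of the trachea during exhalation,
attributed to weakened cartilage rings and/or a weakened posterior trachealis
muscle. Two quantities clinicians cannot measure directly — how much the
tissue properties must degrade, and over what malacic segment length —
determine whether an airway merely narrows or fails catastrophically. This
package implements an organ-scale nonlinear finite-element model of an
idealized pediatric trachea under exhalation pressure to study exactly that:
it quantifies collapse by the mid-length lumen area ratio and identifies the
*mechanism* of severe TM as a snap-through instability of the weakened
anterior arch.

## Constitutive model

All tissues are isotropic, nonlinear elastic (hyperelastic) Ogden solids.
The strain energy per unit reference volume is

$$ W = \sum_t \frac{a_t}{b_t}\left(\bar\lambda_1^{b_t} + \bar\lambda_2^{b_t} +
\bar\lambda_3^{b_t} - 3\right) + \tfrac{1}{2}\,\kappa\,(\ln J)^2, $$

with principal stretches $\lambda_i$, $J = \lambda_1\lambda_2\lambda_3$ and
isochoric stretches $\bar\lambda_i = J^{-1/3}\lambda_i$. The implementation
accepts any number of terms; the default is a single $(a, b)$ pair per
tissue, which is the form the built-in coefficient library uses:

```{r}
default_tissue_library()
```

These one-term coefficients (in MPa) describe preterm-lamb tracheal
cartilage, fibrous tissue and trachealis smooth muscle, and engineered oral
mucosa. Since the underlying experimental curves are not publicly deposited,
the package's synthetic-data generator reconstructs them by sampling the
incompressible uniaxial closed form

$$ \sigma(\lambda) = \sum_t a_t\left(\lambda^{b_t} - \lambda^{-b_t/2}\right) $$

on the plotted strain range 0–0.5 (step 0.01), optionally with additive or
multiplicative Gaussian noise. With multiplicative noise of 5% — a realistic
scatter for soft-tissue testing — refits land at $R^2 \approx 0.97$–$0.999$,
consistent with the quality of fit reported for the original data. What the
generated curves deliberately do **not** emulate is specimen-to-specimen
variability, compression–tension asymmetry, hysteresis or rate dependence;
a passing fit-recovery test therefore demonstrates correctness of the
fitting machinery, not robustness to every pathology of real test data.

**Volumetric behavior.** The source data constrain only the deviatoric
response, so near-incompressibility is imposed by the quadratic-log penalty
with $\kappa = 1000\sum_t a_t$ per tissue (small-strain Poisson ratio
$\approx 0.4995$). This is the standard decoupled treatment in soft-tissue
FE codes. The closed-form uniaxial stress assumes exact incompressibility;
at $\kappa/a = 1000$ the tensor evaluation agrees with it to within about
0.3% for mucosa and 1–2% for the much stiffer cartilage ($b = 16.63$
amplifies the small volumetric strain), which bounds the systematic error
of the penalty treatment.

**Fitting.** `fit_ogden()` minimizes the sum of squared Cauchy-stress
residuals over $(\log a, b)$ with BFGS, multistarted from eight log-spaced
exponents (a local optimizer alone is easily trapped by the strong $a$–$b$
correlation). The fit is deterministic given its seed. Cauchy stress (not
nominal) is used in the residual, matching the stress measure the source
curves are plotted in; $\lambda = 1 + \varepsilon$ with engineering strain
$\varepsilon$. Negative-strain points, if present, enter the same residual.

## Geometry and mesh

The idealized trachea is 50 mm long with a semicircular lumen of diameter
6, 8 or 10 mm: an anterior arch of alternating cartilage rings (2 mm) and
fibrous gaps (1 mm), both 0.8 mm thick, a flat posterior trachealis muscle
(0.8 mm) closing the chord, and a 0.2 mm mucosa lining the whole lumen.
With these widths the 50 mm length tiles exactly as 17 rings + 16 gaps.
Design choices on points the geometric description leaves open:

* the quoted diameter is the **inner** (mucosal) lumen diameter, since the
  lumen is the physiologically quoted dimension; wall layers stack outward,
  and the 0.8 mm wall is additive to the 0.2 mm mucosa;
* the mucosa lines the *entire* lumen, muscle side included — the epithelium
  is anatomically continuous, and self-contact needs a continuous luminal
  surface;
* the muscle attaches under the full width of the arch wall by shared nodes
  (a bonded butt joint at the chord plane), and the band pattern starts and
  ends with a cartilage ring so malacic spans can be centered symmetrically
  at mid-length.

The mesh is all 8-node hexahedra: a half-annulus (mucosa + wall layers)
bonded at $y = 0$ to a flat slab (mucosa on top, muscle below), extruded
axially with a node plane every 1 mm so a cross-section ring of nodes exists
exactly at mid-length. Anterior malacia retargets the $n$ centermost
cartilage rings *and* the fibrous gaps interposed within the span (wall
elements only); posterior malacia retargets muscle elements within a
centered axial span.

## Finite-element solver

Total-Lagrangian formulation, exact spectral Ogden stress and consistent
tangent, full $2^3$ Gauss quadrature for the isochoric term and a
mean-dilatation treatment of the volumetric penalty — $U$ acts on the
volume-averaged Jacobian $\bar J$, the standard cure for volumetric locking
at $\kappa/a = 1000$.

**Element technology.** The collapsing wall is a 1 mm shell in bending, and
plain trilinear hexahedra lock badly there: at any affordable resolution
they overestimate the arch's bending stiffness severalfold and can suppress
buckling entirely. The default element (`h8i`) therefore augments each
hexahedron with three incompatible displacement modes $(1-\xi_i^2)$ in the
style of classical incompatible-mode bricks: mode gradients are evaluated
through the centroid Jacobian and volume-mean corrected (so homogeneous
deformation states are reproduced exactly and the patch test holds), and
the modes are condensed out by *minimizing the element energy* over them at
every evaluation, with a warm start across iterations. Because the
condensed energy is still an exact function of the nodal displacements, the
residual and tangent remain exact derivatives of the discrete energy — the
finite-difference consistency tests in the suite run through the enhanced
element. On the thick-ring benchmark the enhancement cuts the error against
the Lamé solution from ~0.4% to ~0.06% at two elements through the wall;
on the trachea it restores buckling at resolutions where plain elements
(`element = "h8"`, still available) stay artificially patent.

* **Loading.** Exhalation is a net inward pressure on the luminal surface,
  0–40 cm H$_2$O (1 cm H$_2$O = 98.0665 Pa), treated as a follower load on
  the deformed surface. Total airway force is reported as pressure times
  the *undeformed* luminal area, a per-model constant (about 5.04 N at
  40 cm H$_2$O for the 10 mm model).
* **Boundary conditions** (not specified by the geometric description;
  chosen to mimic tracheal continuity and documented so users can vary
  them): both end cross-sections fixed axially, the $x = 0$ symmetry plane
  fixed laterally, and the muscle-midline nodes of the end sections fixed
  vertically. Malacic spans are centered 15+ mm from the ends, limiting
  sensitivity to the end conditions.
* **Contact.** Frictionless node-to-facet penalty self-contact among the
  luminal facets, stiffness $100 \times \max_t a / t_\text{mucosa}$
  (≈ 55 MPa/mm for the intact library). At collapse pressures (∼4 kPa) the
  implied penetrations are ∼$10^{-4}$ mm, far below the 1%-of-mucosa
  audit tolerance. Penetration beyond the mucosa thickness signals a step
  cut rather than silent blow-through.
* **Continuation.** Under *load control* the solver advances pressure with
  adaptive substeps (halve on divergence, grow ×1.5 after easy steps); a
  substep underflow at a limit point terminates as
  `non_convergence_collapse` — deliberately mirroring how severe malacic
  cases fail in practice, and reported as a collapse indicator. The
  *arc-length* mode instead treats the load factor as unknown and traverses
  limit points; both a cylindrical (Crisfield) constraint and single-dof
  control (prescribing the anterior apex deflection, with the load factor
  free) are implemented. Dof control is the default for the trachea because
  the apex deflection is monotone through the snap, which makes the
  continuation markedly more robust than the cylindrical constraint in the
  presence of contact.
* **Damped Newton.** Per-iteration displacement updates are capped (1 mm by
  default). Near a limit point an uncapped Newton step can jump across the
  unstable region onto the post-buckled branch, silently smoothing over the
  instability the analysis is supposed to detect; the cap makes load
  control fail honestly there, as conventional FE codes do.
* **Linear solver.** Sparse symmetrized-Cholesky with a verified
  factorization residual, falling back to sparse LU when the symmetrized
  operator is indefinite or the factorization degrades. The asymmetric part
  (follower pressure, contact) is small relative to the material stiffness;
  the nonlinear residual check is always against the exact assembled
  residual, so the approximation affects iteration counts, never converged
  answers.
* **Tolerances.** Relative residual $10^{-6}$ (against the external-force
  scale), displacement increment $10^{-8}$, 25 Newton iterations per
  substep, initial substep 1 cm H$_2$O, minimum $10^{-3}$. The solver is
  seed-free and bit-for-bit deterministic.

## Collapse quantification

The mid-length luminal node loop, deformed and projected to the section
plane, is an ordered polygon; its shoelace area divided by the intact area
(exactly 1 at zero load, by calibration) is the lumen area ratio. After
contact the loop can self-intersect; the area is then computed on the
largest simple sub-loop — the "remaining open lumen" a manual outline of
the deformed section would capture — with a warning.

Instability onset follows the force–area-ratio extrapolation rule: at each
output step the expected ratio is linearly extended through the two previous
points, and onset is the first step falling more than $\delta$ below that
prediction. No numeric $\delta$ accompanies the rule in its source, so the
package defaults to $\delta = 0.05$ area-ratio units — large enough that the
nearly linear intact descent sampled at 4 cm H$_2$O intervals never fires
(the detector is provably silent on affine data regardless of slope), small
enough to flag the circled drops reproduced by severe anterior malacia. It
is exposed as an argument. Runs terminating by non-convergent collapse
without a detected drop are assigned onset at the final recorded step — the
"starred" non-convergent cases. Onset is reported in both pressure and
force; cross-diameter comparisons use force, since the pressure–force
conversion differs per diameter.

"Wall strain" is the maximum principal Green–Lagrange strain per element,
evaluated at the element corners (with the condensed bending modes
included) and maximized over them — the analog of the nodal fringe plots a
post-processor displays. The distinction matters: with one element through
a 1 mm wall in bending, the element centroid lies on the neutral fiber and
sees essentially zero bending strain, so caption-level wall strains could
never be reproduced from centroid values. A centroid evaluation remains
available (`element_strains(..., at = "centroid")`). The display convention
of the original analysis is unstated, so this choice is documented rather
than inferred.

## Verification strategy and problem sizes

Every layer has an independent oracle: the closed-form uniaxial stress
(material point and single-element reaction), finite-difference energy and
tangent consistency, plane-strain Lamé theory for a thick ring under small
external pressure (5% agreement at matched small-strain moduli), and a
shallow two-bar von Mises truss whose one-dof equilibrium path is scanned
densely in closed form — the arc-length implementation must find the same
limit load to 1% and load control must fail just above it.

Simulation-level checks run at a deliberately coarse analysis scale chosen
by a refinement study: 12 circumferential arc segments, one element through
each wall layer, 1 mm axial planes (about 2,200 enhanced hexahedra and 10k
dof per model; a full collapse run takes minutes on one CPU). This scale
reproduces the collapse phenomenology — near-linear intact descent of the
smaller-diameter models, snap-through of severely weakened anterior arches
at forces within a factor ~2 of a refined mesh (the 10 mm 7-ring
mucosa-severity onset moves from 2.1 N at 12 segments toward lower values
with refinement), and onset-free posterior infolding. With *plain* trilinear
elements, even 16–20 arc segments cannot buckle at all — the locking
analysis above — so an element-technology floor, not merely a resolution
floor, governs these conclusions. Quantitative strain bounds carry the
scaled-down-mesh caveat. With the enhanced element the still coarser
8-segment mesh reproduces the 12-segment classifications and onset forces
to within about 10%, so the test suite exercises collapse behavior there
(minutes for the whole panel) while the analysis runs use 12 segments.

Two model-level findings from this study shape how the package is
exercised. First, the **intact 10 mm model reaches its own limit point near
24 cm H$_2$O (≈3 N)**. This is structural, not numerical: the limit
*decreases* slightly under mesh refinement (it converges from above), is
insensitive to end conditions (fully clamping both end rings moves it by
only ~1 cm H$_2$O), and agrees with classical ring-buckling theory —
$p_{cr} \approx 3EI/R^3$ with the cartilage section ($E \approx 3ab/2
\approx 2.7$ MPa, $t = 0.8$ mm) gives ≈28 cm H$_2$O at $R = 5$ mm, with
$R^{-3}$ scaling putting the 8 mm and 6 mm intact models safely beyond
40 cm H$_2$O (≈55 and ≈130). The larger airway's greater collapse
propensity thus emerges directly from the mechanics. Second, because the
anterior arch of the 10 mm model fails near 3 N regardless of posterior
properties, the posterior-weakening series is run on the **6 mm model**,
where the intact arch is two orders of magnitude below its buckling
pressure and the trachealis mechanism is isolated; the source analyses do
not state which diameter their posterior series used.

Traversing the snap itself: under displacement-controlled continuation the
10 mm mucosa-severity model loads to ≈2.1 N, then the apex descends at
essentially constant load while the walls fold into contact — at this
resolution the mathematical limit point is smoothed into a steep,
contact-stabilized branch, and the continuation eventually stalls inside
the fold rather than returning down a distinct unstable branch. Wall
strains at 2 N on this traversed branch are far above the 45% scale that
characterizes collapsed airways, while posterior models stay in a
qualitatively different, low-strain regime.

## Known limitations

* Nonlinear *elastic* tissue only: no viscoelasticity (collapse happens
  fast relative to tissue relaxation, and no pediatric viscoelastic data
  exists to calibrate it), no anisotropy, no tension–compression asymmetry.
* Idealized geometry: no taper, no open-angle variation of the cartilage
  rings, no image-derived patient anatomy.
* Quasi-static snap-through: the jump to the post-buckled branch is
  traversed by continuation, not resolved dynamically.
* No airflow coupling: pressure is prescribed, not computed from flow.
* The posterior "weakened" coefficients $(a = 1, b = 7)$ and $(a = 1,
  b = 1)$ are *stiffer* than intact muscle at small strain ($\mu = ab/2$)
  while far less strain-stiffening at large strain; they are implemented
  literally as specified, and the ambiguity is flagged here rather than
  silently corrected.

## Reproducing the headline numbers

`scripts/acceptance.R` recomputes, from scratch: the mucosa closed-form
stress at 50% strain; the recovered cartilage coefficients from a
noise-free synthetic refit; the wall strain at 2 N on the traversed
collapse branch of the 10 mm anterior mucosa-severity model; and the wall
strain at 5 N of the posterior $(a=1, b=1)$, 32 mm model where that load is
sustained — per the ring-buckling analysis above, the 10 mm model's
anterior arch fails near 3 N, so that quantity has no equilibrium state to
report at this geometry reading. See the README for invocation.
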