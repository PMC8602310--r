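---
title: "Interface-matching inverse FE recovery of plaque material parameters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface-matching inverse FE recovery of plaque material parameters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Structural simulation of an atherosclerotic coronary artery needs two
ingredients: the heterogeneous tissue morphology (which modern intravascular
imaging supplies) and per-tissue constitutive parameters (which it does
not). `plaquefe` implements an inverse finite-element method that recovers
multi-parameter constitutive laws for up to five intra-plaque tissue classes
— healthy wall ("artery"), mixed, fibrous, lipid and calcium — from only two
observed geometric states of the same vessel segment, imaged at two known
intraluminal pressures.

The central idea is the objective function. Matching only macro-morphology
(lumen diameters, or the inner and outer wall surfaces) under-determines a
multi-tissue parameter vector: tissues confined to the wall interior barely
influence those observables. Matching *micro*-morphology does better: every
pair of node sets — one per tissue class plus the inner surface
$\mathcal{J}$ and outer surface $\mathcal{O}$ — that share nodes defines a
tissue interface, and each interface contributes its own error term. For an
interface between sets $X$ and $Y$, the error is the directional
average nearest-node distance

$$\epsilon^{X,Y} = \frac{1}{N^{\mathrm{target}|X,Y}}
 \sum_{j} \min_{k}\; \bigl| r_j^{\mathrm{target}|X,Y} -
   r_k^{\mathrm{def}|X,Y} \bigr|,$$

taken from the target interface nodes to the nearest node of the same
interface in the simulated (deformed) geometry. The multi-objective fitness
$\delta_{MO}$ is the vector of all interface errors; the single-objective
value $\delta_{SO}$ is their sum. The error is implemented exactly as
printed — directional, not symmetrized — which is testable: padding the
deformed interface with far-away nodes leaves it unchanged.

Recovery solves $\mathbb{Y}^\ast = \arg\min_{\mathbb{Y}} \delta$ where each
candidate $\mathbb{Y}$ is pushed through the forward operator
$\mathcal{S}$: deform the base mesh by the pressure differential
$\Delta P = P_{\mathrm{target}} - P_{\mathrm{base}}$ (default 60 mmHg,
converted at 1 mmHg = 0.133322 kPa) with both ends constrained
longitudinally, and compare against the target geometry.

## Constitutive models

Two models of increasing complexity are supported, mirroring the two
verification studies:

* **Linear elastic** (`mode = "linear"`): Hooke's law with one Young's
  modulus per tissue, infinitesimal-strain kinematics. The material is
  treated as nearly incompressible with a fixed Poisson ratio of 0.49 (the
  incompressible limit is approached but not reached, keeping a
  displacement-only formulation). 4 parameters are free: E for artery,
  mixed, fibrous and lipid. Calcium is held fixed — it occupies well under
  1% of the wall in the default lesion, too sparse to identify.
* **Yeoh hyperelastic** (`mode = "yeoh"`): strain energy
  $W = C_{10}(\bar I_1 - 3) + C_{20}(\bar I_1 - 3)^2 + C_{30}(\bar I_1-3)^3$
  plus a volumetric penalty $\tfrac{\kappa}{2}(J-1)^2$, total-Lagrangian
  finite-strain kinematics, follower pressure on the deforming lumen.
  $\bar I_1$ is the first *deviatoric* invariant
  ($J^{-2/3}\,\mathrm{tr}\,F^TF$); the textual definition of $I_1$ via
  principal stresses in the source material is dimensionally inconsistent
  with $(I_1 - 3)$ and is read as the standard stretch-based invariant.
  8 parameters are free ($C_{10}, C_{20}$ for the four soft classes).
  $C_{30}$ is fixed at its assigned value: simulated uniaxial tests
  (`yeoh_uniaxial_fe()`) show the stress response departs from the
  $C_{30}$-free curve only beyond ~20% strain, and the pressurized vessel
  stays below that (the solver reports `max_strain`, with a warning
  threshold at 0.2). A third mode (`"yeoh9"`) frees calcium $C_{10}$ as
  well, for lesions whose calcium volume exceeds 1%.

Ground-truth values and one-order-of-magnitude search bounds for every
parameter ship in `material_bounds()` (kPa throughout). Calcium's assigned
$C_{10}$ of 1270 kPa has no published range; the `yeoh9` mode uses
[127, 12700], consistent with the one-order-of-magnitude philosophy of the
other ranges.

### Volumetric penalty

The penalty modulus defaults to $\kappa = 1000\,\mu_0$ with
$\mu_0 = 2C_{10}$. In the vessel problem wall stresses are on the order of
10 kPa, so relative volume changes stay near $10^{-3}$, while the Newton
landscape remains tractable. A penalty scaled instead to the full
polynomial ($C_{20}$ exceeds $C_{10}$ by two orders of magnitude for
arterial tissue) makes the penalty's geometric nonlinearity dominate the
residual at 1% strain and destroys Newton convergence under load control.
The one-element uniaxial verification harness is the opposite regime —
displacement control, stretches up to 1.3, hydrostatic stresses of hundreds
of kPa — so `yeoh_uniaxial_fe()` defaults to the stiffer
$\kappa = 1000\,(C_{10}+C_{20}+C_{30})$ there, where displacement stepping
tolerates it. Because verification targets are generated by the same
forward operator (the inverse-crime setting), the penalty choice cancels
out of recovery accuracy.

## Forward solver

Meshes are quadratic simplices — 6-node triangles in the 2D plane-strain
desk mode, 10-node tetrahedra in 3D — chosen to mitigate volumetric locking
near incompressibility. Element assembly (small-strain stiffness,
finite-strain residual and consistent tangent) is compiled code; linear
systems go through sparse LU/Cholesky from the Matrix package.

* In linear mode the per-tissue unit-modulus stiffnesses are assembled once
  per mesh and recombined per candidate ($K(\mathbb{Y}) = \sum_t E_t K_t$),
  so one evaluation is a single sparse solve.
* In Yeoh mode the solver uses Newton-Raphson with a residual-monotone
  backtracking line search, load continuation with a secant predictor and
  adaptive step control (initial step 1/4 of the load, growing after easy
  steps, halving on failure), and the previous converged state as a warm
  start across nearby candidates during optimization. Failed solves at
  extreme parameter combinations are not errors of the method: the global
  stage assigns them infinite fitness, the local stage rejects the step.

Boundary conditions: axial displacement is fixed on both end caps (3D);
because the luminal pressure on a closed inner surface is self-equilibrated,
the remaining in-plane rigid modes are removed by two point constraints
that carry no load (one node pinned, one diametrically opposite node fixed
tangentially). The base geometry is treated as stress-free at
$P_\mathrm{base}$; zero-pressure pre-stress recovery is out of scope and
acknowledged as a limitation below.

Verification anchors: the homogeneous annulus under internal pressure
matches the plane-strain Lamé closed form to well under 1% at the reference
refinement (64 x 8), with monotone convergence under refinement; the
one-element uniaxial response matches the incompressible Yeoh closed form
to about 0.1% at stretches up to 1.3; rotating geometry and load rotates
the solution.

## Two-stage optimization

The inverse landscape is non-convex, so a stochastic global stage precedes
a deterministic local one:

1. **NSGA-II** on $\delta_{MO}$ (population 24; 7 generations for the
   linear study, 24 for the Yeoh study), initialized by Latin hypercube
   sampling. Free parameters are optimized in a log10 scaling of their
   search range mapped to the unit cube — ranges span one to two orders of
   magnitude. Genetic operators are the canonical defaults: simulated
   binary crossover (probability 0.9, eta 15) and polynomial mutation
   (probability 1/n, eta 20).
2. The individual with the minimum $\delta_{SO}$ *across all generations*
   (ties: earliest evaluation) seeds an **SQP-style local stage**, budgeted
   at 40 function evaluations with a successive-objective termination
   residual of $10^{-9}$; one function evaluation costs $n+1$ forward
   simulations (the point plus its forward-difference derivatives), and
   that product is the stage's total simulation budget. SQP codes of the
   NLPQLP family that fit this contract are proprietary, so the stage is
   implemented here from scratch: a damped Gauss-Newton step built from
   the forward-difference Jacobian of the interface-error *vector* (the
   same $n$ perturbed simulations, used at full information), Marquardt
   scaling so weakly sensitive directions still move, an accepted step
   extended by doubling while the objective keeps dropping, and momentum and
   coordinate line-search fallbacks for the cone-complex valleys the
   nearest-node objective develops (see known limitations). The finite-difference step (default $10^{-3}$
   in scaled space) contracts with the trust scale but stays above
   $10^{-6}$, the level at which forward-solver tolerance noise would
   corrupt the derivatives.

## The synthetic vessel phantom

No clinical imaging ships with this package. `generate_synthetic_vessel()`
emulates the *output* of image-based model generation: a watertight labeled
mesh of a thick-walled annular segment (default inner radius 1.5 mm, mean
wall 1 mm) with parametric intramural inclusions painted over an artery
background by centroid membership. The default phenotype is a concentric
annulus with a fibrous cap region (~19%) enclosing a lipid pool (~13%),
dispersed mixed-tissue deposits (~3%), and a calcific speck (~0.3%,
deliberately under the 1% threshold that triggers the calcium-exclusion
rule); an eccentric wall (lumen offset toward the plaque, thickness
varying around the circumference as diseased vessels present) is available
through `lumen_offset`. Element labeling from an annotated point cloud
(`label_elements()`, nearest-cloud-point-to-centroid with lowest-index tie
break) is also provided, mirroring how image annotations are transferred
onto a patient mesh.

Two phantom-design points deserve emphasis:

* **Identifiability drives the phantom shape.** In a thin annular band
  each tissue sees a nearly uniform strain $x$, and a two-parameter law
  $C_{10}x + C_{20}x^2$ then admits near-compensating parameter
  combinations — probes of the objective landscape showed shallow valleys
  with parameter errors of tens of percent at objective values of
  $10^{-3}$–$10^{-4}$ mm. Patient lesions mitigate this by dispersing each
  tissue over varied mural depths and strain levels; the default phantom
  does the same where it matters most, placing the mixed tissue (the
  smallest soft class) as two lobes at different depths. A verification
  phantom must be an identifiable problem instance, or it tests the
  optimizer against a degeneracy the method never claimed to resolve.
  Eccentric walls (`lumen_offset`) spread strain further but couple the
  linear moduli into curved valleys that slow the bounded local stage;
  the concentric default is the better-behaved verification instance.
* **What passing tests do not show.** The phantom is a straight tube with
  piecewise-constant, internally homogeneous tissue regions, no
  measurement noise beyond the modeled Gaussian displacement noise, no
  imaging artifacts, no meshing discrepancy between base and target (both
  share one topology), and no pre-stress. Recovery accuracy here is an
  upper bound on what clinical data would allow; the noise and
  pressure-perturbation studies probe robustness, not realism.

## Verification studies and desk-scale problem sizes

The verification harness (`run_study()`, `compare_objective_modes()`)
reproduces the structure of the in-silico studies: targets generated by the
same forward solver at the assigned ground truth (so the global optimum is
known and exactly zero), repeated seeded recoveries, and percent-error
reporting `100 |recovered - assigned| / assigned` per free parameter,
aggregated as mean ± SD with medians alongside.

Problem sizes are chosen for a single-CPU desk scale: the default 2D
cross-section (48 x 6 divisions, 576 quadratic triangles, ~1250 nodes) for
both constitutive modes, population 24 with 7 (linear) to 24 (Yeoh)
generations and the 40-evaluation local budget. A linear recovery takes
seconds, a Yeoh recovery about a minute. On patient-scale 3D meshes the
same budgets imply hour-scale runtimes; the scaled-down phantom keeps
every structural element (heterogeneity, interface objective, two-stage
optimization, noise model) while shrinking only the mesh.

Noise enters exactly as specified: each displacement component is scaled by
$1 + z$, $z \sim \mathcal{N}(0,\; n \cdot \max|u|)$ with the maximum taken
over all components of the field (the literal elementwise reading; a
per-node-vector variant was considered and rejected), and the noisy target
is $\Omega_{\mathrm{base}} + U_{\mathrm{noisy}}$. Pressure perturbation
scales the generating $\Delta P$ by ±5% or ±10% while recovery assumes the
nominal value; in the linear regime the induced modulus bias equals the
perturbation to first order, which the study reproduces.

## Objective-mode baselines

For the comparison against macro-morphological matching,
`objective = "surface"` restricts the error set to the inner and outer
surfaces, and `objective = "diameter"` compares minimum and maximum lumen
diameters on evenly spaced cross-sections (default 10 slices; a single
slice in 2D). The diameter of a nodal contour is implemented as the
min/max caliper (Feret) extent over a fan of directions — a
"chord through the centroid" is ill-defined on a sparse contour — and the
mode's two objective entries are the mean absolute min- and max-diameter
discrepancies over slices. These details are package choices; the source
protocol does not specify them.

## Numerical choices and degenerate inputs

* Centroid-labeling ties break to the lowest cloud-point index; exact
  nearest-neighbour ties in the interface error accept any minimizer (the
  distance is identical), with the kd-tree resolving to the lowest index.
* Interfaces with fewer than 3 shared nodes are dropped with a warning — a
  one-node interface makes the average degenerate.
* End caps are identified by axial coordinate within `1e-6` of the segment
  length; inner vs. outer surface by connected components of the lateral
  boundary ranked by mean radius.
* Meshes are validated on construction: connectivity bounds, strictly
  positive element measures (minimum isoparametric Jacobian per element),
  manifold boundary (any facet shared by more than two elements is an
  error naming the facet).
* Degenerate generator specs (zero wall thickness, inclusions outside the
  wall annulus, resolutions below 8 x 2) are rejected with diagnostics.
* VTU/MSH round-trips write coordinates at 17 significant digits and are
  bit-exact on IEEE doubles; the MSH writer emits one entity block per run
  of equal labels so element order survives the round-trip.

## Known limitations

* The 40-evaluation local budget is part of the protocol, and on the
  desk-scale phantom it is the binding constraint for the 8-parameter
  recovery: most seeds recover every Yeoh parameter to within a few
  percent, but some runs end the budget while still descending a shallow,
  kink-dense valley, leaving tens of percent of error in the
  lowest-sensitivity parameter (typically a C20 of a sparse intramural
  tissue, or the small artery C10 — the same parameters that carry the
  largest errors in the full-scale study). Landscape probes show a
  monotone descent path from these stalled iterates to the exact optimum,
  so the limitation is optimization budget, not identifiability.

* The base state is assumed stress-free; recovering the zero-pressure
  configuration first would remove this assumption and is the natural next
  step for clinical data.
* Isotropic models only; anisotropic fiber-reinforced laws (GOH) are out
  of scope, as are viscoelasticity, contact, FSI and dynamics.
* The 2D plane-strain mode is a desk-scale testing device, not a clinical
  claim; out-of-plane effects need the 3D mode.
* Identifiability of parameters for very sparse tissues is inherently
  weak; the calcium-exclusion rule (volume < 1%) is a blunt but effective
  guard, and `yeoh9` should only be used when calcium is prevalent.
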