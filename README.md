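# plaquefe

Inverse finite-element characterization of heterogeneous atherosclerotic
vessel walls from two imaged pressure states.

## The problem

High-fidelity simulation of diseased coronary arteries needs patient-specific
material properties for each plaque tissue class — healthy wall ("artery"),
mixed, fibrous, lipid and calcified tissue — but in vivo imaging gives
morphology, not mechanics. `plaquefe` recovers multi-parameter constitutive
laws for all soft tissue classes at once from just two labeled geometries of
the same vessel segment acquired at different intraluminal pressures
(a base state Ω_base at P_base and a target state Ω_target at P_target).

The method inverts the forward relation

    Ω_target = S(Ω_base, ΔP, Y),    ΔP = P_target − P_base

for the material parameter vector Y by minimizing a *micro-morphological*
objective: for every pair of node sets (one per tissue class, plus the inner
surface 𝒥 and outer surface 𝒪) sharing nodes, an interface error

    ε^{X,Y} = mean over target-interface nodes of the distance
              to the nearest deformed-interface node

is computed; the multi-objective fitness δ_MO is the vector of all interface
errors and the single-objective value δ_SO is their sum. Matching *all*
tissue interfaces — not just the wall surfaces or lumen diameters — is what
makes parameters of predominantly intramural tissues (lipid, mixed)
recoverable from a single pressure differential.

Supported constitutive models: linear elastic (one modulus per tissue,
4 free parameters) and Yeoh hyperelastic
W = C10(Ī₁−3) + C20(Ī₁−3)² + C30(Ī₁−3)³ (8 free parameters: C10/C20 for
the four soft classes; C30 is held fixed because the response is
insensitive to it below ~20% strain; calcium is excluded below 1% volume,
or included as a 9th parameter otherwise). Optimization is two-stage:
Latin-hypercube-initialized NSGA-II on δ_MO, then an SQP-style
forward-difference refinement of the best individual (by δ_SO, across all
generations) within the one-order-of-magnitude search bounds.

No clinical data ships with the package: a synthetic-vessel generator
builds labeled plane-strain sections or 3D tubes with parametric intramural
inclusions (fibrous cap, lipid pool, dispersed mixed deposits, calcific
speck), emulating the output of image-based model generation, and the
verification harness reproduces the in-silico study design: targets
simulated at known ground-truth parameters, repeated seeded recoveries,
displacement-noise and pressure-perturbation sensitivity, and comparison
against surface- and diameter-matching baselines.

## Worked example

```r
library(plaquefe)

# a labeled plane-strain vessel section: fibrous cap, lipid pool,
# mixed deposits, calcific speck over an artery background
mesh <- generate_synthetic_vessel(synth_vessel_spec())
round(tissue_volume_fractions(mesh), 2)
#>  artery   mixed fibrous   lipid calcium
#>   64.43    3.32   19.28   12.49    0.49

# in-silico target at the ground-truth linear moduli, dP = 60 mmHg
ld  <- load_case(60, 120)
tgt <- make_target(mesh, ld, pack_parameters("linear"))

# two-stage recovery (NSGA-II population 24 x 7 generations + SQP)
rec <- recover_materials(mesh, tgt$target, ld, mode = "linear",
                         config = optimizer_config(seed = 1))
round(rec$values, 1)
#> artery.E  mixed.E fibrous.E  lipid.E
#>      300      500      1200       15
signif(percent_errors(rec), 3)
#> artery.E  mixed.E fibrous.E  lipid.E
#> 1.40e-05 9.55e-05  2.05e-05 7.50e-06
```

The recovered moduli land on the assigned values (artery 300, mixed 500,
fibrous 1200, lipid 15 kPa) to within about 1e-4 percent: with a
noise-free target generated by the same forward solver, the true parameter
vector is an exact zero of the objective, and the report quantifies how
close the optimizer gets. `run_study()` repeats this over a seed list and
aggregates percent errors; `run_study(..., noise = 0.05)` perturbs the
target displacement field with multiplicative Gaussian noise first, and
`compare_objective_modes()` runs paired recoveries under the interface,
surface and diameter objectives.

A thin command-line wrapper over these functions is installed at
`inst/cli/plaquefe.R` (subcommands `generate`, `forward`, `make-target`,
`recover`, `noise-study`, `pressure-study`, `compare-modes`, `report`),
driven by a YAML configuration file.

## Scope

The package verifies the method in silico. OCT acquisition, deep-learning
tissue classification, surface reconstruction from clinical point clouds,
zero-pressure (pre-stress) geometry recovery, anisotropic constitutive
models and fluid-structure interaction are out of scope; see the methods
vignette (`vignettes/interface-matching.Rmd`) for the model, its
assumptions, numerical choices and limitations.
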