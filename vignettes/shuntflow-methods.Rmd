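---
title: "Models and methods in shuntflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in shuntflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shuntflow)
```

`shuntflow` connects three layers of a modified Blalock-Taussig shunt (MBTS)
analysis: hyperelastic constitutive models for the graft and aortic wall,
estimation of their constants from uniaxial tensile tests, and a
reduced-order pulsatile flow solver for an idealized
aorta-shunt-pulmonary-artery network whose wall mechanics derive from those
constitutive choices. This vignette documents the models, the numerical
choices, and what the package's synthetic data can and cannot show about
real measurements.

## Constitutive layer

All materials are treated as incompressible (`J = 1`): the deviatoric
invariants are then the plain invariants of the right Cauchy-Green tensor,
`I1 = sum(lambda_i^2)`, `I2 = sum(lambda_i^2 lambda_j^2)`, `I3 = 1`, and
the volumetric penalty term of the five-parameter Mooney-Rivlin form is
carried in the parameter record but never evaluated. Four strain-energy
densities are implemented, in MPa:

* **Mooney-Rivlin (5 parameters)**
  `W = c10 (I1-3) + c01 (I2-3) + c20 (I1-3)^2 + c11 (I1-3)(I2-3) + c02 (I2-3)^2`.
  Coefficient signs are unconstrained: fitted expanded-PTFE graft constants
  legitimately include negative `c10`, so material stability over the working
  stretch range is a diagnostic (`drucker_stability_report()`), not a
  constructor constraint.
* **Yeoh (3 parameters)** `W = sum_i ci0 (I1-3)^i` with `c10 > 0`.
* **Ogden (up to 3 terms)**
  `W = sum_p mu_p/alpha_p (lambda_1^alpha_p + lambda_2^alpha_p +
  lambda_3^alpha_p - 3)`, shear modulus `mu = (1/2) sum mu_p alpha_p > 0`.
  With one term and `alpha = 2` this is the neo-Hookean solid; with two
  terms and `alpha = (2, -2)` it is a two-term Mooney-Rivlin material —
  both identities are regression-tested.
* **Holzapfel-Gasser-Ogden (HGO)**
  `W = c10 (I1-3) + k1/(2 k2) sum_a (exp(k2 <E_a>^2) - 1)` with the fiber
  strain measure `E_a = kappa (I1-3) + (1 - 3 kappa)(I4_a - 1)` and
  tension-only Macaulay bracket `<x> = max(x, 0)`. `I4_a` is the squared
  stretch along fiber family `a`; `kappa` in `[0, 1/3]` is the dispersion
  (0 = aligned, 1/3 = isotropic).

Two conventions for the `I4` coefficient circulate, `(1 - 3 kappa)` and
`(1 + 3 kappa)`. The package defaults to the standard `(1 - 3 kappa)`
because only then does `kappa = 1/3` make the fiber term direction
independent — the stated isotropy limit; the alternative is available via
`hgo(..., convention = "plus")`. Fiber families default to a symmetric
`+/- 45 degree` pair because no fiber angle is available for the pediatric
aorta; the angle is a constructor argument, measured from the
circumferential axis in the wall tangent plane (loading axis for uniaxial
states).

Uniaxial nominal (first Piola-Kirchhoff) stress is derived analytically on
the incompressible path `(lambda, lambda^-1/2, lambda^-1/2)` for every
model; a central-difference derivative of `W` along the same path is kept as
an independent oracle in the tests (relative agreement `< 1e-6` over
`lambda` in `[0.5, 2.5]`). The experimental stress axis is interpreted as
nominal stress computed from the undeformed tube-wall cross-section
(`pi * d * h`), the convention of tensile machines; Cauchy stress is a
conversion (`lambda * P`).

One subtlety: the HGO fiber term is tension-only, so the uniaxial tangent
modulus is one-sided at `lambda = 1`. `small_strain_shear_modulus()`
therefore reports the tension-side linearization (`E = 6 c10 +
k1 sum <g_a>^2`, `mu = E/3`), and the numerical tangent oracle
(`uniaxial_tangent()`) uses a second-order one-sided difference.

## Tensile fitting

`fit_material()` minimizes the sum of squared stress residuals with bounded
Levenberg-Marquardt from 16 Latin-hypercube starts plus a mid-range start
(seed 20220407 by default). Bounds default to `[-10, 10]` MPa for
Mooney-Rivlin/Yeoh coefficients, `[-30, 30]` for Ogden exponents,
`k2 in (0, 100]`, `kappa in [0, 1/3]`.

Success is declared **in curve space**, not parameter space: the
five-parameter Mooney-Rivlin family is rank-deficient on a single uniaxial
path, so very different coefficient vectors reproduce the same curve.
The identifiability diagnostic is the condition number of the
column-normalized model Jacobian at the solution (the collinearity
"condition index"). The default flag threshold is 30, the classical cutoff
for severe collinearity; on synthetic graft data the three-parameter Yeoh
fit scores ~20 while the five-parameter Mooney-Rivlin fit scores in the
thousands, so the diagnostic separates the two regimes by two orders of
magnitude. Parameters aligned with near-null singular directions are
reported as weakly identified; nothing is refused.

`initial_modulus()` is an ordinary least-squares slope of nominal stress
against engineering strain through the preload-corrected origin over a
small-strain window (default `lambda <= 1.05`); `ultimate_strength()`
returns the stress maximum and its stretch, flagging records without a
marked rupture. Load rate is carried as metadata only: graft strength is
rate-insensitive over the tested range, so rate never enters the model.
Preload re-referencing (`rereference_preload()`) is offered but not applied
automatically, since generated data are already consistently referenced.

## Synthetic data

No tensile curves or patient geometries are distributed, so the
`tensile_spec()`/`generate_tensile()` pair and `build_network()` produce
every input. The tensile generator evaluates a generating constitutive model
on a stretch grid (default 100 points from 1 to 1.6, the working range of
the graft tests), adds i.i.d. Gaussian stress noise (default sd 0.05 MPa,
a few percent of the terminal stress), and optionally appends a rupture
point. It is seeded and bit-reproducible. What it emulates: smooth
loading-branch curves of specimens with stated geometry. What it does not:
unloading hysteresis, specimen-to-specimen heterogeneity, grip and slack
artifacts, or rate effects — so passing recovery tests demonstrates
correctness of the estimation machinery, not robustness to every
experimental pathology.

The inlet waveform is a piecewise-smooth pulse: quarter-sine rise to
1.4 m/s at 0.09 s, smooth fall to the diastolic baseline (default 0 m/s) at
end-systole 0.22 s, constant through diastole to the 0.5 s period. The
published boundary conditions fix the pulmonary outlet at a constant
20 mmHg but give no numbers for the systemic outlet profile; a synthetic
physiologic pulse from 80 to 120 mmHg, phased with the inlet, is supplied
and configurable (`systemic_pressure_profile()`).

The network is an idealized pediatric tree, not patient CT geometry: an
ascending aorta (radius 6 mm), three arch branches, a descending aorta, and
a pulmonary side fed exclusively by a 3.5 mm diameter, 0.35 mm wall
expanded-PTFE shunt, placed centrally (ascending aorta to pulmonary trunk),
right (left subclavian to right pulmonary artery) or left (brachiocephalic
trunk to left pulmonary artery). Default segment lengths are multiples of
10 mm so that uniform grid refinement with spacings 10, 5, 2.5 mm halves
every segment's spacing exactly — this keeps grid-convergence studies clean.
All dimensions and materials are configurable per segment.

## Reduced-order hemodynamics

The solver integrates the 1-D area-flow equations per segment,

`A_t + Q_x = 0`,
`Q_t + (alpha Q^2/A)_x + (A/rho) p_x = -8 pi mu Q/(rho A)`,

with a parabolic-profile closure (`alpha = 4/3`, Poiseuille friction) and a
quasi-static algebraic wall law `p(A)` per segment: wall inertia is dropped
and the interface conditions of the full coupled fluid-wall problem are
satisfied by construction of the tube law and friction term. Blood is
Newtonian (density 1060 kg/m^3, viscosity 0.0035 Pa s); a hook for a
shear-rate-dependent viscosity exists in the design but constant viscosity
is the only implemented rheology.

**Tube laws.** For a hyperelastic wall under plane stress, fixed axial
stretch 1 and wall incompressibility, the circumferential Cauchy stress is
`sigma_theta = lambda W'(lambda)` on the path
`(lambda, 1, 1/lambda)`, and membrane equilibrium with the *deformed*
thickness `h/lambda` and radius `lambda r0` gives
`p(A) = (h/(r0 lambda)) W'(lambda)`, `lambda = sqrt(A/A0)`. This form is
exactly the derivative of the wall strain energy per unit vessel length with
respect to lumen area, which the tests verify against numerical
differentiation; using the reference thickness instead would break that
energy consistency at first order in `lambda - 1`. The linear-elastic wall
uses the standard thin-shell law
`p = (E h/(1-nu^2)) (lambda-1)/(lambda r0)`, whose linearization yields the
Moens-Korteweg speed `c = sqrt(E h/(2 rho r0 (1-nu^2)))` — reproduced by
the solver within 3% in the tests. Elastic stability `dp/dA > 0` is checked
at construction over a stated stretch window.

**Scheme.** Second-order explicit MacCormack predictor-corrector in `(A, Q)`
with an adaptive CFL-limited step (CFL 0.8 default); laws are tabulated on a
dense stretch grid for speed. Boundary and junction nodes are closed by
characteristics: the exact generalized Riemann function
`F(A) = integral c(a)/a da` is tabulated per law (the familiar `u +/- 4c`
form holds only for square-root tube laws), and the outgoing characteristic
variable `W = u +/- F(A)` is sampled at the foot of the characteristic at
the old time level with the friction source integrated along the path —
a second-order closure that the steady tests rely on (mass imbalance at
boundaries falls from ~1e-4 to ~1e-8 of the through-flow compared with
nearest-node extrapolation).

**Junctions.** Each junction solves, by Newton iteration with warm starts,
exact mass conservation plus a pressure relation per connected end around a
junction pressure node: ends discharging into the junction transmit
`p + (1-K) rho u^2/2` and receiving ends satisfy ideal total-pressure
continuity. The default is `K = 1` everywhere — a "mixing plenum" in which
an incoming jet's dynamic head is dissipated. This is a deliberate deviation
from lossless total-pressure continuity, for a structural reason: with
ideal-pressure systemic outlets, a lossless junction lets reverse branch
flow lower the junction static pressure by its own dynamic head, a
quadratic feedback that linear friction cannot bound — in trials the
brachiocephalic branch ran away to ~19 m/s and -1400 mmHg. Physically, the
jet head at an anastomosis or branch ostium is lost to turbulent mixing that
a laminar 1-D model cannot represent; `K = 1` restores that dissipation and
puts the shunt jet at `u ~ sqrt(2 dp/rho) ~ 4.5 m/s`, the clinically
observed MBTS jet scale, with cycle-mean shunt flow near 2.2 L/min. `K` is
configurable per segment (`network_spec(junction_loss = ...)`), with `K = 0`
recovering the classical lossless closure.

**Convergence.** Runs integrate whole cardiac cycles until the
cycle-to-cycle relative L2 change of pressure and flow drops below a
tolerance (default 1e-3, typically reached on the third cycle from the
quiescent pressure-flooded initial state) or `n_cycles` is reached;
unconverged solutions are flagged and refused by the metric layer unless
forced. Mass accounting over the final cycle (inflow, outflow, lumen
storage) is attached to every solution.

## Metrics and scenario comparison

Wall shear stress uses the parabolic closure `tau_w = 4 mu Q/(pi R^3)` — a
deliberately lower-fidelity analogue of 3-D near-wall gradients; TAWSS is
the final-cycle mean of `|tau_w|` (the averaging window and magnitude
convention are a package choice, as none is standard). Von Mises wall
stress uses the thin-walled biaxial vessel state (`sigma_theta = pR/h`,
`sigma_z = pR/2h`, radial ~ 0, so `sigma_vm = sqrt(3)/2 sigma_theta`); 3-D
bending and anastomotic stress concentrations are expressly not reproduced,
and only directions of effect are tested. Radial displacement is
`sqrt(A/pi) - r0`. Relative deviations between scenario series are pointwise
`|x1-x2| / max(|x1|, |x2|, 1e-12)`, maximized over the cycle.

`compare_scenarios()` crosses aorta materials (isotropic Ogden versus
anisotropic HGO), shunt materials (linear elastic versus hyperelastic) and
the three placements on identical networks and forcing. For the
isotropic/anisotropic comparison the HGO aorta is built by
`hgo_aorta()` with its tension-side small-strain modulus matched to the
Ogden target, so differences isolate anisotropy rather than overall
stiffness. At this reduced order the anisotropy effect on shunt flow is of
the order of a few percent and is largest for the central placement —
the same direction and ranking as the full 3-D comparison, though not its
magnitudes, which depend on patient geometry.

## Problem sizes and defaults

Default runs use 5 mm node spacing (4-node minimum per segment), CFL 0.8,
2 ms output sampling, and up to 6-8 cycles with the 1e-3 periodicity
tolerance; validation limits (Poiseuille, Moens-Korteweg, junction balance)
run on single tubes and a three-segment Y-junction at the same settings.
The grid-refinement study uses fixed two-cycle runs at 10/5/2.5 mm with a
3-node minimum so the refinement is exactly uniform.

## Known limitations

* The network is a 1-D idealization: no anastomosis angles, no secondary
  flow, no 3-D stress concentrations; quantitative stresses are
  pressure-vessel values, not finite-element fields.
* Systemic outlets are ideal pressure sources (no terminal resistance or
  compliance), so flow splits are governed by the network and the junction
  loss model rather than by downstream vascular beds.
* The wall law is quasi-static and axially untethered (axial stretch fixed
  at 1); wall inertia and longitudinal coupling are dropped.
* The HGO parameter set for the pediatric aorta is a stiffness-matched
  construction, not a fitted anisotropic dataset: published anisotropic
  aortic constants were reported under parameter names that do not map
  one-to-one onto the HGO form used here, so the package accepts HGO
  parameters only under their standard names.
* Tension-only fibers make tangents one-sided at the reference state; all
  linearized quantities are tension-side by convention.
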