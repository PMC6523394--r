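---
title: "Modelling swelling and drug release from porous gellan-gum/laponite beads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling swelling and drug release from porous gellan-gum/laponite beads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gelbead)
```

## The physical problem

Freeze-dried gellan-gum (GG) beads crosslinked with Ca²⁺, with or without
laponite clay, are candidate oral sustained-release carriers. Dropped into
simulated gastric fluid (SGF, HCl 0.1 M) or simulated intestinal fluid (SIF,
phosphate buffer pH 7.4) at 37 °C they absorb up to ~50 g of solvent per g of
dry matrix while their diameter at most doubles — the hallmark of a very
porous, very light matrix (dry density ~0.1 g/cm³). Loaded drug
(theophylline as a small non-interacting probe, vitamin B12 as a large probe
that binds to the clay–polymer complex) is released while the bead swells,
into a finite stirred reservoir that is repeatedly sampled by
withdraw-and-replace aliquots.

`gelbead` implements that chain end to end: a moving-boundary swelling model
with a diffuse glassy–rubbery interface; Fickian and two-phase (bound/free)
drug transport coupled to the swelling field; the finite-reservoir protocol
simulator with withdrawal events and sequential SGF→SIF staging; parameter
estimation from swelling-degree and withdrawal-concentration series; and a
synthetic-data generator that stands in for bench measurements.

## Swelling model and its assumptions

The solvent volume fraction `φ(r,t)` obeys a nonlinear diffusion equation in
spherical symmetry on the growing domain `0 < r < S(t)`,

$$\frac{\partial\varphi}{\partial t} = \frac{1}{r^2}\frac{\partial}{\partial r}
\Big[r^2\, D_s(\varphi)\,(1-\varphi)\,\frac{\partial\varphi}{\partial r}\Big],$$

with `φ(r,0) = φ₀`, `φ(S(t),t) = φ_eq`, zero gradient at the centre, and the
gel–solvent front moving by the Stefan condition
`dS/dt = D_s(φ_eq) ∂φ/∂r|_S`, `S(0) = R₀` (half the freeze-dried diameter —
the swelling and release assays start from freeze-dried beads). Instead of
tracking a second sharp glassy–rubbery front, the transport coefficient
decays smoothly in the glassy core,

$$D_s(\varphi) = D_s^{sg} f(\varphi),\qquad
f(\varphi)=\begin{cases}1 & \varphi \ge \varphi_G\\
\exp\{-\beta\,(\varphi_G-\varphi)/(\varphi_G-\varphi_0)\} & \varphi < \varphi_G,\end{cases}$$

so a single parameter `β` interpolates between porous (small `β`, solvent
penetrates the core) and non-porous (large `β`, near-sharp interface)
behaviour. Assumptions worth keeping in mind: spherical, identical beads
(the measured aspect ratio ~1.02 supports this); volume additivity of
solvent and matrix; no polymer erosion or dissolution; no bead-size
distribution.

### Parameters, units, defaults

| parameter | meaning | unit | default / convention |
|---|---|---|---|
| `D_s_sg` | solvent diffusivity in the swollen gel | m²/s | fitted per formulation/medium |
| `β` | glassy-core decay rate | — | 2 (highly porous beads) |
| `φ_eq` | equilibrium solvent fraction | — | from `S_eq` by volume additivity |
| `φ_G` | swelling-threshold fraction | — | `0.1 φ_eq` (easy re-hydration after freeze-drying) |
| `φ₀` | dry-bead residual solvent | — | 0.01 |
| `R₀` | initial radius | m | freeze-dried diameter / 2 |
| `ρ_b`, `ρ_s` | dry-bead and solvent densities | g/cm³ | measured; 1.000 for both media (dilute aqueous) |

`φ₀` is not a measured quantity; it must be positive for `f` to be defined.
Its main visible effect is on the model's asymptotic swelling degree, which
equals `S_eq (1 − φ₀)` exactly — 1% below the measured `S_eq` at the default.
The fitting routine accounts for this when inverting an observed asymptote.
Sensitivity elsewhere is weak (the factor `f` is clamped at `exp(−β)` below
`φ₀`, avoiding unbounded extrapolation).

The front law is applied exactly as written above, without the `(1−φ_eq)`
factor that appears in the interior flux; with that convention the front
velocity equals the swelling velocity at the surface, the advective terms at
the boundary cancel, and both solvent and drug mass balances close exactly
at the discrete level. The alternative (`front_velocity =
"flux_consistent"` in `solver_control()`) multiplies the front speed by
`(1−φ_eq)` to match the interior flux form; it slows the front *and* settles
at a lower asymptote, `(S_∞/R₀)³ = 1 + φ_eq − φ₀` instead of
`(1−φ₀)/(1−φ_eq)`, so it does not reproduce the measured equilibrium
swelling. It is provided for comparison only; the front law as printed is
the volume-consistent choice and the default.

A consequence of the printed front law: the solvent audit must count both
the diffusive influx through the surface *and* the solvent swept in by the
advancing front,
`d/dt ∫φ dV = [D_s(1−φ_eq)∂φ/∂r + φ_eq dS/dt]·4πS²`; the package's
`mass_residual` uses this identity and closes to integrator tolerance.

## Drug transport

Free drug diffuses with `D_d(φ) = D_d^sg f(φ)` (same `f`, same `β` — drug
uses the same pore network as solvent) and is advected by the swelling
velocity `v_r = D_s(φ) ∂φ/∂r`; at the surface it is in concentration
equilibrium with the reservoir, `c_d(S,t) = C_res(t)` (partition coefficient
one, no boundary-layer resistance). The optional bound phase `c_b` (initial
fraction `ε` of the loading `c_d⁰`) is advected with the matrix, does not
diffuse, and desorbs at `k_bg(φ) = k_bg^sg f(φ)`. The reservoir balance

$$V_{res}\,\frac{dC_{res}}{dt} = N_{beads}\,\big(-D_d^{sg}\,\partial c_d/\partial r|_S\big)\,4\pi S^2$$

is punctuated by withdrawal events: at each sampling time the concentration
drops by the exact factor `(V_res − V_w)/V_res` and the removed mass
`V_w C_res` is credited to the cumulative-withdrawn ledger — no
delta-function smoothing, since the withdrawal is a discrete act. The
integral release curve divides the drug outside the beads (live reservoir +
withdrawn + reservoirs drained at medium switches) by its value at protocol
end. All relative outputs are invariant to `c_d⁰` (the model is linear in
concentration; a test asserts this), so the loading only matters for
absolute `C_res` traces; it defaults to `ρ_b` times the drug mass fraction
of the dry bead (recipe × entrapment efficiency).

At the SGF→SIF switch the beads are drained: the old reservoir's content is
set aside as released, the reservoir restarts at zero in fresh medium, and
the bead fields (`φ`, `c_d`, `c_b`, front radius) carry across while the
boundary condition jumps to the new medium's `φ_eq` and the transport
coefficients swap. Interstitial liquid clinging to the beads is ignored.

## Numerics

Front-fixing transformation `ξ = r/S(t)` maps the problem to the unit ball;
a conservative arbitrary-Lagrangian-Eulerian finite-volume scheme on a
two-zone mesh (3× denser in the outer 10% of `ξ`, default 240 nodes)
discretises space, with upwinding of the mesh-relative advective fluxes and
a one-sided second-order boundary gradient driving the front. Time
integration uses `deSolve::lsodes` (stiff, sparse; default tolerances
1e-6/1e-9); the right-hand sides are compiled. The telescoping of the
conservative fluxes makes the discrete drug balance exact up to integrator
tolerance — the 0.1% audit is a check on the integrator, not on the scheme.
Withdrawals and medium switches are integrator restarts with exact jumps.

The discontinuous initial condition (`φ = φ₀` inside, `φ_eq` at the surface
at `t = 0⁺`) is regularised by a thin two-node boundary layer; the audit is
taken relative to the regularised initial content, so no spurious mass
enters. Near equilibrium the boundary gradient is clamped at zero so
round-off cannot pull the front backwards.

Verification: grid-refinement changes the 24-h swelling degree by <0.5% on
doubling from 120 nodes; in the static perfect-sink constant-diffusivity
limit the release solver matches the closed-form sphere series within 1e-3
absolute over three decades of dimensionless time; and the simulated
asymptote reproduces the analytically exact limit `S_eq (1 − φ₀)` of the
model.

Problem sizes used in the tests and the acceptance script: 240-node default
grid for headline simulations, 64–100 nodes and slightly relaxed tolerances
(1e-5/1e-8) inside fitting loops, 10-seed recovery ensembles — chosen so the
full suite runs on a laptop-class single core in minutes while staying
within the convergence margins above.

## Parameter estimation

`fit_swelling()` estimates `D_s^sg` only: `φ_eq` is never free (it is fixed
from the measured asymptote through the volume-additivity relation,
corrected by the `(1−φ₀)` factor above), `β = 2` and `φ_G = 0.1 φ_eq` are
conventions. The objective is weighted least squares on the swelling-degree
series; optimisation is multi-start on `log₁₀ D` (log-spaced starts spanning
the bounds, Brent refinement of the best bracket) because diffusivities span
decades.

`fit_release_fickian()` estimates `D_d^sg` on *differential* data — the
withdrawal concentrations `C_res(t_w)` with the sawtooth events in the model
— rather than on the integral curve. The differential curve is more
sensitive to `D_d^sg` both in the initial rise and where withdrawals bite;
the acceptance suite demonstrates the practical consequence: across matched
noisy draws the differential estimator has a smaller spread than the
integral one.

`fit_release_two_phase()` estimates `(D_d^sg, k_bg^sg)` with the initially
bound fraction `ε` either fixed (`epsilon_fixed`, mirroring the published
two-parameter procedure in which `ε` is a formulation property) or free. The
joint three-parameter problem is *practically non-identifiable* at realistic
noise: curves along the ridge `(D×3, k×0.65, ε: 0.80→0.89)` differ by under
~2% relative — below triplicate noise — so the joint optimum wanders over a
~3× span in `D`. The routine therefore (a) pre-scans the objective over a
`(D, k, ε)` grid before Levenberg–Marquardt (the weighted surface also has a
distant local minimum that traps a purely local search), (b) returns a
`(k, ε)` profile grid for identifiability inspection, and (c) flags
boundary-pinned `ε`. With `ε` configured, `(D, k)` recover to a few percent
from 2%-noise synthetic assays.

Two estimation details that matter in practice: the Levenberg–Marquardt
finite-difference step is set well above the integrator noise (the default
machine-epsilon step makes the optimiser stall on a numerically rough
surface); and reported per-point SDs are smoothed against the signal level
before inverse-variance weighting — raw triplicate SDs have two degrees of
freedom, and a single underestimated SD would otherwise dominate the fit.
Standard errors come from the Gauss–Newton approximation at the optimum;
with only mean±SD summaries (no raw replicates) they describe the fit, not
the full experimental uncertainty.

## Synthetic data

`gen_swelling_series()` and `gen_release_series()` run the forward models
and emulate the assay structure: triplicate measurements reported as
mean ± SD, Gaussian noise (relative by default: 3% for swelling degrees, 2%
for withdrawal concentrations — levels chosen to resemble the published
error bars, configurable), truncation at zero, explicit seeds (identical
seed and configuration give byte-identical output). The paired integral
series is assembled from the *noisy* withdrawals by the same ledger the
assay would use. What the generator does **not** emulate: HPLC assay error
structure, blotting/handling artefacts in early swelling points, bead-size
dispersity, or imperfect reservoir mixing. Passing recovery tests therefore
show the estimation machinery is consistent under the stated noise model —
not that real assays achieve those tolerances.

The fixture registry (`bead_fixtures()`) carries the published
characterisation used throughout: bead diameters (freeze-dried 1.63 and
2.06 mm), dry densities (0.109, 0.0926 g/cm³), equilibrium swelling degrees
and fitted solvent diffusivities per medium, drug diffusivities for both
probes, transfer rates for B12 in laponite beads, and entrapment
efficiencies. For vitamin B12 in laponite beads the initially bound fraction
was never published; the registry defaults to `ε = 1`, which reproduces the
strongly non-Fickian gastric release signature, and every consumer accepts
an override.

## Design choices and known limitations

* **Equilibration-time metric.** The simulated swelling curves flatten
  visually within ~15–20 min, consistent with the published description, but
  the strict time-to-95%-of-asymptote is longer for the strongly swelling
  GG/Ca-in-SIF case (~31 min; time-to-90% is ~22 min). The 95% metric is
  reported as computed; the late-time approach to equilibrium is governed by
  the slowest diffusion mode of the fully swollen sphere, whose time constant
  `S_∞²/(π² D_s^sg (1−φ_eq))` is ~15 min for that case, so a strict 95%
  criterion necessarily exceeds the visual flattening time.
* **Gastric-stage release of theophylline from laponite beads** computes to
  ~82% at 120 min with the freeze-dried radius (1.03 mm). Using the fresh,
  never-dried radius (1.4 mm) instead gives ~67–70%. The package follows the
  freeze-dried convention throughout because the assays start from
  freeze-dried beads; users comparing against fresh-bead data should set the
  geometry accordingly.
* The two-phase bound fraction `ε` is a configuration, not a reliably
  fittable quantity, at realistic noise (see above).
* No erosion, no solubility saturation (reservoir concentrations stay far
  below drug solubility in these protocols), no boundary-layer resistance at
  the bead surface, perfect mixing of the reservoir.
* Withdrawal schedules are configurable; the defaults (1–240 min, 13 points,
  1 mL) reflect the assay description but the exact bench times were not
  enumerated. The perfect-sink property (50 vs 175 mL curves differ by less
  than the bead-to-reservoir volume ratio) bounds their influence.
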