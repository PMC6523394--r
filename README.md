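# gelbead

Mechanistic swelling and drug-release modelling for highly porous
polysaccharide beads — gellan gum (GG) crosslinked with calcium, with or
without laponite clay — in simulated gastric and intestinal fluids (SGF, SIF).

Freeze-dried GG beads are extremely light (dry density ~0.1 g/cm³) and soak
up tens of times their weight in solvent while their diameter barely doubles.
Classical sharp-front swelling models handle this poorly; `gelbead`
implements a moving-boundary model with a *diffuse* glassy–rubbery interface
and couples it to drug transport under realistic dissolution protocols. It is
aimed at formulation scientists who want to extract transport parameters from
bench swelling/release assays, and to predict gastrointestinal release from
independently fitted parameters.

## The models

**Swelling.** The solvent volume fraction `φ(r, t)` in a spherical bead obeys

    ∂φ/∂t = (1/r²) ∂/∂r [ r² D_s(φ) (1 − φ) ∂φ/∂r ],   0 < r < S(t)

with `φ = φ_eq` at the gel–solvent front `S(t)`, symmetry at the centre, and
the front moving as `dS/dt = D_s(φ_eq) ∂φ/∂r |_S` (a Stefan condition). The
glassy core is not tracked as a second sharp front; instead the diffusivity
decays smoothly below the swelling threshold `φ_G`:

    D_s(φ) = D_s^sg · f(φ),   f(φ) = exp{ −β (φ_G − φ)/(φ_G − φ_0) }  for φ < φ_G,  else 1

`β` encodes porosity (β ≈ 2 for these highly porous beads; β ≈ 8 recovers
sharp-interface, non-porous behaviour). The equilibrium fraction comes from
the measured swelling degree `S_eq` by volume additivity:
`x_eq = 1 − 1/(1+S_eq)`, `φ_eq = (x_eq/ρ_s) / ((1−x_eq)/ρ_b + x_eq/ρ_s)`.

**Release.** Free drug diffuses with `D_d(φ) = D_d^sg f(φ)` and is advected
by the swelling velocity; an optional bound phase (initial fraction `ε` of
the loading, attached to the polymer/clay complex) transfers to the free
phase at rate `k_bg(φ) = k_bg^sg f(φ)`. The finite, perfectly mixed reservoir
evolves by a macroscopic balance with instantaneous withdrawal/replacement
events (the sawtooth of real dissolution assays), and the integral release
curve `M_t/M_∞` is assembled by the withdrawal-corrected ledger. The Thiele
modulus `Φ² = k_bg^sg R₀² / D_d^sg` identifies the rate-controlling step:
`Φ² ≫ 1` is diffusion-controlled (Fickian, early-time exponent ≈ 0.5), `Φ²`
of order 10 or less gives the non-Fickian signature (exponent > 1).

Numerics: front-fixing transformation `ξ = r/S(t)`, conservative ALE
finite volumes on a boundary-refined mesh, stiff sparse integration
(`deSolve::lsodes`), compiled right-hand sides. Drug mass is conserved to
better than 0.1%, and the solver matches the closed-form constant-diffusivity
sphere series to ≤ 1e-3 in its static perfect-sink limit.

## Worked example

Simulate the in-vitro gastrointestinal protocol (120 min in 100 mL SGF with
1-mL withdrawals, then 120 min in 50 mL SIF) for theophylline-loaded
GG/LAPO/Ca 0.3% beads, all parameters from the packaged registry:

```r
library(gelbead)

sol <- simulate_gi_fixture("tph", "gg_lapo")
sol
#> <release_solution> GG/LAPO/Ca 0.3%, 2 stage(s), t: 0..240 min
#>   released fraction at end: 0.9971
#>   drug-mass residual: 7.39e-06
round(100 * released_at(sol, c(120, 240)), 1)
#> [1] 82.0 99.7
```

82% of the loaded theophylline leaves in the gastric stage and the rest in
the intestinal stage; the drug-mass audit (bead content + reservoir +
withdrawn aliquots vs initial load) closes to 7e-6. Fitting a solvent
diffusivity from a synthetic triplicate swelling assay:

```r
f   <- fixture_formulation("gg")
sp  <- fixture_swelling("gg", "SIF")        # truth: D_s^sg = 1.5e-9 m^2/s
ser <- gen_swelling_series(f, medium("SIF"), sp,
                           noise = noise_model(level = 0.03, seed = 1))
fit <- fit_swelling(ser, f, medium("SIF"), S_eq = 45.80)
tidy(fit)
#> # A tibble: 1 × 3
#>   term   estimate std.error
#>   <chr>     <dbl>     <dbl>
#> 1 D_s_sg  1.54e-9   3.43e-11
```

`autoplot()` methods draw the swelling curve, the sawtooth differential and
integral release curves, and fit residuals.

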