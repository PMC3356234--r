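---
title: "The cytokine-balance model of cartilage lesion expansion and abatement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cytokine-balance model of cartilage lesion expansion and abatement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondrosim)
```

## The biological picture

Articular cartilage is populated by chondrocytes fixed in extracellular
matrix. An acute injury kills the cells inside a small disc by necrosis.
The necrotic debris releases alarmins (DAMPs, `M`), which switch nearby
healthy chondrocytes (`C`) into a catabolic state (`S_T`). Catabolic cells
synthesize TNF-α (`F`) and reactive oxygen species (`R`). TNF-α feeds the
inflammation back (more switching, matrix degradation releasing further
DAMPs, apoptosis of sick cells) — the pro-inflammatory arm is
self-amplifying, and on its own it spreads the lesion without bound.

The counterweight is erythropoietin (EPO, `P`): healthy cells signaled by
ROS begin, after a synthesis delay of about a day, to produce EPO; EPO
rescues sick cells that have expressed the EPO receptor (the EPOR-active
state `S_A`, entered with a shorter delay after TNF-α signaling), and —
the model's key closure — once local EPO exceeds a critical level the
healthy-to-catabolic switch shuts off. The outcome of an injury is decided
by the race between the outward-diffusing pro-inflammatory front and the
EPO field building up behind and ahead of it.

## Model structure

Nine fields live on a circularly symmetric two-dimensional domain,
resolved in the radial coordinate only. Four chemical concentrations
diffuse, decay, and are produced by cells:

* `dR/dt = ∇·(D_R ∇R) − δ_R R + σ_R S_T`
* `dM/dt = ∇·(D_M ∇M) − δ_M M + σ_M D_N + δ_U U · sat(F, λ_F)`
* `dF/dt = ∇·(D_F ∇F) − δ_F F + σ_F S_T`
* `dP/dt = ∇·(D_P ∇P) − δ_P P + σ_P C · sat(R(t−τ₂), λ_R) · Λ/(Λ+F)`

with `sat(x, λ) = x/(λ+x)`. EPO production uses the *current* healthy
density with ROS sensed a delay `τ₂` ago, and is attenuated by TNF-α
through the inhibition constant `Λ`. The matrix `U` is degraded by TNF-α
(`dU/dt = −δ_U U · sat(F, λ_F)`), and degraded matrix releases DAMPs (the
same term appears as a source for `M`).

The immobile cell states exchange density:

* healthy → catabolic at `(β₁ sat(M, λ_M) + β₂ sat(F, λ_F)) · H(P − P_c)`,
  where the gate `H` is 1 while `P < P_c` and 0 once local EPO reaches the
  critical level `P_c`;
* catabolic → EPOR-active at `γ`, driven by the catabolic density and
  TNF-α saturation at `t − τ₁`;
* EPOR-active → healthy at `α · sat(P, λ_P)`;
* apoptosis: catabolic cells require TNF-α *and* DAMPs jointly
  (`ν sat(F) sat(M)`), EPOR-active cells TNF-α (`μ_SA sat(F)`); the dead
  accumulate in a ledger `D_A` that feeds back into nothing;
* necrotic cells decay to inert at `μ_DN`, shutting down the primary DAMP
  source.

Because every switching term moves density between compartments, the sum
`C + S_T + S_A + D_A` is exactly conserved pointwise — cells change state,
never number. The test suite asserts this at machine precision over
ten-day runs; it is the model's bookkeeping invariant.

Without the threshold gate (`H ≡ 1`, available as
`h_identically_one()`), the alarmin/TNF-α loop is self-amplifying and the
healthy population collapses — the diagnostic that motivates gating the
switch on EPO. With EPO pathways active, the `H ≡ 1` variant does not
drive the healthy pool literally to zero: EPO-driven reversion recycles a
small healthy pool (about 10–15% of the initial population at the
reference calibration), so "exhaustion" in the diagnostic means decline to
that recycled floor; the corresponding test asserts monotone penumbra
growth while the healthy pool remains above 15% of its initial value.

## Numerics

**Space.** The domain `[0, r_max]` is partitioned into `n_nodes` equal
annuli (finite volumes). The radial diffusion operator
`(1/r) ∂_r (r ∂_r ·)` is discretized conservatively with edge-radius
weighted fluxes and zero-flux conditions at the center (symmetry) and the
outer boundary. The scheme is second order, exactly conservative
(area-weighted sums of the operator vanish), self-adjoint under the
area inner product, and exact for quadratics away from the outer
boundary. Defaults: `r_max = 5` mm (20× the injury radius) and
`n_nodes = 200` (`Δr = 0.025` mm); a warning fires if any chemical's
boundary value ever exceeds 1% of its spatial maximum. In the unabated
regime the lesion eventually floods any finite domain, so that warning is
expected there.

**Time.** The semi-discrete system is a delay-differential system with
two constant lags. It is integrated by the method of steps with an
explicit Bogacki–Shampine 2(3) embedded pair and a cubic-Hermite
continuous extension for history queries — the same architecture as the
classic `dde23` solver. Steps are capped at the shortest delay, so
delayed arguments always land in already-accepted history, and mandatory
step endpoints are placed at the lag combinations `i·τ₁ + j·τ₂`
(`i + j ≤ 3`), where the delays propagate derivative discontinuities.
That placement makes delay causality exact in the computed solution:
with zero history, `S_A` is identically zero before `τ₁` and `P`
identically zero through `τ₂`, to the last bit.

Default tolerances are `rtol = 1e-6`, `atol = 1e-8`, with hourly output
via dense interpolation. The integrator contains no randomness; rerunning
a scenario reproduces the trajectory bit for bit on one platform.

**Positivity.** The equations preserve non-negativity in the continuous
limit for the reference regime, but two numerical caveats apply. First,
the cubic dense output can undershoot by about `rtol` times the field
scale near the delay-activation kinks, so output values are clipped to
zero when they are within `10·(atol + rtol·max|field|)` of zero and an
error is raised beyond that. Second, the delayed drain
`γ S_T(t−τ₁) sat(F(t−τ₁))` can genuinely push `S_T` negative — a property
of the equations, not the solver — when `γ·sat(F)·τ₁` approaches the
oscillation threshold `1/e` of the linear delay equation; the reference
calibration keeps that product below ≈ 0.2 even under doubling of `γ`.

**The discontinuous gate.** `H` is implemented exactly as a discrete
switch by default; no event location is attempted, and the error
controller absorbs the crossings. A logistic smoothing
(`chondro_params(h_sharpness = k)`) is available as a numerical device
for stiff configurations; it is off by default and not part of the model.

## The reference calibration

No quantitative parameter values are available for this model, so the
package ships a documented reference set, in normalized units (time in
hours, lengths in mm, densities in cells/mm², concentrations scaled so
all half-saturation constants are 1). Every value is a calibration —
`param_table()` marks provenance — chosen once so that the two regimes
the model exists to contrast both occur from the same initial condition
(a 0.25 mm necrotic disc in a healthy field of `C0 = 100` cells/mm²,
observed for ten days):

* **No EPO** (`sigma_P = 0`, all else identical): the inflammatory front
  crosses the domain within the ten days and the healthy population is
  decimated (below 5% of its initial total by day 10), still expanding at
  the end of the run.
* **With EPO**: identical dynamics for the first day (the delays see to
  that — no pathway has activated), then EPO crosses `P_c` ahead of the
  front, the penumbra stalls at a fixed radius (drifting less than 5%
  between days 7 and 10), and the healthy population recovers.

The choices that matter, and why:

* The two delays are the only physiology-anchored values: `τ₁ = 12` h
  (upper end of the reported 8–12 h for EPOR expression) and `τ₂ = 24` h
  for EPO synthesis onset.
* The front is driven by the DAMP/matrix loop (`β₁ = 0.5/h` dominant,
  `β₂ = 0.005/h` minor): TNF-α degrades matrix, degraded matrix releases
  DAMPs, DAMPs convert healthy cells. Keeping the direct TNF-α conversion
  pathway minor is what makes `β₂` perturbations innocuous and prevents
  spurious re-ignition of inflammation far from the lesion.
* Signaling ranges `√(D/δ)` are ordered: TNF-α and DAMPs are short-range
  (≈ 0.06 mm), ROS intermediate (≈ 0.7 mm), EPO long-range (≈ 1.4 mm).
  ROS must out-range TNF-α so that healthy cells beyond the inflamed
  annulus — where EPO production is not TNF-suppressed — are recruited as
  EPO producers, and EPO must out-range everything so the gate closes
  *ahead* of the advancing front. With short-range EPO the gate only
  closes behind the front and abatement degenerates into a global, late
  shutdown rather than a fixed stall radius.
* `Λ = 400` puts the TNF-α inhibition of EPO production deep in its
  weak-coupling regime (TNF-α concentrations stay below ≈ 6). Abatement
  timing responds strongly (about 1.5 days per factor of two) to any
  multiplicative change in EPO production, so a strongly-coupled `Λ`
  could not be robust under the sweep protocol; the robustness reported
  for `Λ` is itself evidence of weak coupling.
* Reversion is slow (`α = 0.005/h`) and EPOR activation moderate
  (`γ = 0.015/h`), so the penumbra persists visibly through day 10 while
  the healthy population recovers on the week scale.

## Metrics and regime classification

`lesion_summary()` reduces a trajectory to per-hour scalars: the lesion
radius (outermost radius where `C < θ_C·C0`, linearly interpolated,
default `θ_C = 0.5`), the penumbra's inner/outer radii (support of
`S_T + S_A > θ_S·C0`, default `θ_S = 0.05`), population integrals and
chemical maxima. `classify_regime()` labels a run *expanding* if the
lesion radius still grows faster than `ε = 0.01` mm/day over the final
three days, *abated* if it does not but a penumbra persists, and
*resolved* otherwise. `abatement_day()` is the start of the last daily
window in which the lesion radius grew by more than `ε` — `Inf` if it
never stops growing. All thresholds are exposed as arguments; the
defaults above are used throughout the tests.

## The sensitivity protocol

`sensitivity_table()` perturbs one constant at a time over `[0, 2z]`
(`[0.05z, 2z]` for the half-saturation constants, `Λ` and `α`, which must
stay strictly positive), reruns the with-EPO scenario at each value, and
assigns one qualitative label per direction by deterministic rules on the
endpoint statistics (`sensitivity_labels()` documents the thresholds;
peak lesion radius, abatement day, peak penumbra content and
healthy-population recovery are the discriminating statistics). The
reduced resolution used for the full table (`n_nodes = 100`, 5 points per
parameter, about 70 simulations) keeps the whole protocol in desk time while
leaving every label unchanged from spot checks at full resolution.

Two behaviors deserve comment. Decreasing the ROS production rate is
*exactly* equivalent to increasing its saturation constant by the same
factor, because ROS enters the model only linearly in its own equation
and through `sat(R, λ_R)`; the suite asserts this equivalence at solver
precision. And decreasing `γ` or `α` collapses the healthy population's
recovery (the penumbra, starved of EPOR-active cells or of reversion,
stops responding to EPO) while leaving the stall radius essentially
unchanged: the lesion extent is set by the race between the front and
the EPO ramp, and the two channels through which `γ` and `α` act on that
race — more catabolic cells produce both more TNF-α (faster front) and
more ROS (faster EPO ramp) — cancel almost exactly. The protocol labels
these directions `slower-recovery`. A regime in which reduced reversion
also *shrinks* the penumbra was not found for the printed equations; the
package reports what the model does.

## What the synthetic scenarios do and do not show

All inputs are generated by the package itself; there is no external
data. The scenarios emulate the geometry (circular symmetry, sharp-edged
necrotic disc), the delay structure, and the qualitative regime contrast
of the injury response. They do not emulate: mechanical loading or
cartilage geometry, cell motility, the IL-1β pathway, stochastic cell
behavior, or measured concentration scales (units are normalized).
Passing tests therefore demonstrate internal correctness of the solver
and the stated regime phenomenology — not quantitative agreement with any
experiment.

## Reduced problem sizes used by the automated checks

The acceptance checks run the two canonical scenarios at the reference
resolution (`n_nodes = 200`, ten days) and the sensitivity table at
`n_nodes = 100` with 5 points per parameter; unit tests use smaller grids
(40–60 nodes) and shorter horizons where the property under test does not
depend on the canonical calibration. These sizes are the package's
standing choices for desk-time reproducibility.
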